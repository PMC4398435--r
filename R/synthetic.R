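## Ground-truth world generator. Every pipeline input can be produced here
## with known truth: multi-period climate stacks with prescribed future
## shifts, virtual species with known suitability functions, land cover,
## elevation, dispersal values, a phylogeny, and trait/response tables. All
## generators are pure functions of (parameters, seed).

# Row-normalized Gaussian band matrix used for separable smoothing.
smoothKernel <- function(n, sd) {
  K <- outer(seq_len(n), seq_len(n), function(i, j) exp(-(i - j)^2 / (2 * sd^2)))
  sweep(K, 1L, rowSums(K), `/`)
}

gaussianField <- function(nr, nc, sd_cells) {
  M <- matrix(stats::rnorm(nr * nc), nr, nc)
  S <- smoothKernel(nr, sd_cells) %*% M %*% t(smoothKernel(nc, sd_cells))
  S / stats::sd(S)  # unit variance after smoothing
}

# Translate a matrix poleward (toward row 1 = north) by k rows, extending
# the southern edge with its last row.
translateNorth <- function(m, k) {
  if (k == 0L) return(m)
  nr <- nrow(m)
  idx <- pmin(seq_len(nr) + k, nr)
  m[idx, , drop = FALSE]
}

#' Generate multi-period synthetic climate stacks
#'
#' Builds four variables on a regular grid: `temp` (latitudinal gradient),
#' `prec` (longitudinal gradient), `seas` (mixed gradient) and `soil`
#' (pure smoothed noise), each with Gaussian-filtered spatial noise. The
#' past stack is the current one with a small cool offset on `temp`; future
#' stacks apply the prescribed per-period shift: an additive offset per
#' variable and/or a poleward translation of the whole field in degrees.
#'
#' @param dims c(nrow, ncol) grid size (default 200 x 200).
#' @param res cell size in degrees (default 0.1).
#' @param xll,yll grid origin (default 0, 0).
#' @param shifts named list per future period (`f2020s`, `f2050s`,
#'   `f2080s`), each `list(offset = c(var = delta, ...), translate_deg = d)`.
#'   Default: progressive warming of +1, +2, +3 units on `temp`.
#' @param past_offset additive offset defining the past period (default
#'   `c(temp = -0.3)`).
#' @param noise_sd per-variable noise standard deviations.
#' @param noise_scale smoothing length of the noise in cells.
#' @param seed integer seed.
#' @return named list of [EnvStack-class]: past, current, f2020s, f2050s,
#'   f2080s.
#' @export
genClimate <- function(dims = c(200L, 200L), res = 0.1, xll = 0, yll = 0,
                       shifts = list(
                         f2020s = list(offset = c(temp = 1)),
                         f2050s = list(offset = c(temp = 2)),
                         f2080s = list(offset = c(temp = 3))),
                       past_offset = c(temp = -0.3),
                       noise_sd = c(temp = 0.5, prec = 2, seas = 1,
                                    soil = 1),
                       noise_scale = 5, seed = 1L) {
  set.seed(seed)
  nr <- dims[1L]; nc <- dims[2L]
  lat <- matrix(yll + (nr - row(matrix(0, nr, nc)) + 0.5) * res, nr, nc)
  lon <- matrix(xll + (col(matrix(0, nr, nc)) - 0.5) * res, nr, nc)
  base <- list(
    temp = 25 - 1.0 * lat,
    prec = 100 + 2.0 * lon,
    seas = 10 + 0.3 * lat - 0.2 * lon,
    soil = matrix(50, nr, nc))
  noise <- lapply(names(base), function(v)
    noise_sd[[v]] * gaussianField(nr, nc, noise_scale))
  names(noise) <- names(base)
  current <- Map(`+`, base, noise)
  apply_shift <- function(layers, shift) {
    out <- layers
    if (!is.null(shift$offset))
      for (v in names(shift$offset)) out[[v]] <- out[[v]] + shift$offset[[v]]
    if (!is.null(shift$translate_deg) && shift$translate_deg != 0) {
      k <- as.integer(round(shift$translate_deg / res))
      out <- lapply(out, translateNorth, k = k)
    }
    out
  }
  past <- current
  for (v in names(past_offset)) past[[v]] <- past[[v]] + past_offset[[v]]
  out <- list(past = envStack(past, "past1900_1949", xll, yll, res),
              current = envStack(current, "current1950_2000", xll, yll, res))
  for (p in names(shifts))
    out[[p]] <- envStack(apply_shift(current, shifts[[p]]), p, xll, yll, res)
  out
}

#' Synthetic elevation and land-cover rasters
#'
#' Elevation is anti-correlated with temperature (cool cells high) plus
#' smoothed noise, in metres. Land cover bins a mix of precipitation and
#' noise into integer classes.
#'
#' @param stack the current-period [EnvStack-class].
#' @param n_classes number of land-cover classes (default 4).
#' @param seed integer seed.
#' @return list `elevation` (numeric matrix, m) and `landcover` (integer
#'   matrix of classes 1..n_classes).
#' @export
genTerrain <- function(stack, n_classes = 4L, seed = 1L) {
  set.seed(seed)
  d <- dim(stack)
  temp <- getLayer(stack, "temp")
  prec <- getLayer(stack, "prec")
  elev <- pmax((max(temp, na.rm = TRUE) - temp) * 180 +
                 120 * gaussianField(d[1L], d[2L], 4), 0)
  z <- prec + 15 * gaussianField(d[1L], d[2L], 4)
  q <- stats::quantile(z, probs = seq(0, 1, length.out = n_classes + 1L),
                       na.rm = TRUE)
  lc <- matrix(cut(z, breaks = q, labels = FALSE, include.lowest = TRUE),
               d[1L], d[2L])
  list(elevation = elev, landcover = lc)
}

#' Coefficients of a Gaussian niche on one variable
#'
#' Convenience for building virtual-species truth: the logistic-quadratic
#' suitability `plogis(h - (x - opt)^2 / (2 w^2))` expressed as intercept,
#' linear and quadratic coefficients on `var`.
#'
#' @param var variable name.
#' @param opt niche optimum (variable units).
#' @param width niche width w.
#' @param height logit suitability at the optimum (default 3).
#' @return named coefficient vector usable in [genVirtualSpecies()].
#' @export
gaussianNicheCoefs <- function(var, opt, width, height = 3) {
  out <- c(height - opt^2 / (2 * width^2),
           opt / width^2, -1 / (2 * width^2))
  names(out) <- c("(Intercept)", var, paste0(var, "^2"))
  out
}

truthSuitability <- function(stack, coefs) {
  d <- dim(stack)
  eta <- matrix(coefs[["(Intercept)"]], d[1L], d[2L])
  for (nm in setdiff(names(coefs), "(Intercept)")) {
    if (grepl("\\^2$", nm)) {
      v <- sub("\\^2$", "", nm)
      eta <- eta + coefs[[nm]] * getLayer(stack, v)^2
    } else if (grepl("\\*", nm)) {
      vs <- strsplit(nm, "*", fixed = TRUE)[[1L]]
      eta <- eta + coefs[[nm]] * getLayer(stack, vs[1L]) *
        getLayer(stack, vs[2L])
    } else eta <- eta + coefs[[nm]] * getLayer(stack, nm)
  }
  stats::plogis(eta)
}

#' Generate a virtual species: truth rasters and an occurrence table
#'
#' The truth suitability is a logistic function of the climate layers with
#' known coefficients. Presence cells are drawn (without replacement)
#' proportional to truth suitability, optionally multiplied by a sampling
#' bias weight map; a configurable fraction is assigned to the pre-1950
#' period with locations drawn against the past stack's truth. Records are
#' placed at cell centers with years uniform in the period and coordinate
#' precisions drawn so that a known subset violates the 2 km resolution
#' filter.
#'
#' @param name species name.
#' @param coefs named truth coefficients (see [gaussianNicheCoefs()];
#'   feature names may be `var`, `var^2`, `var1*var2`, `(Intercept)`).
#' @param stacks list with `past` and `current` [EnvStack-class] stacks.
#' @param n_presences number of records (default 200).
#' @param pre1950_fraction fraction of records in the pre-1950 period
#'   (default 0.15).
#' @param coarse_fraction fraction of records given precision > 2 km
#'   (default 0.1).
#' @param bias optional non-negative weight matrix multiplying the sampling
#'   probability.
#' @param seed integer seed.
#' @return list: `truth` (current-period suitability matrix), `truth_past`,
#'   `records` (occurrence data.frame with species, lon, lat, year,
#'   precision_km, source), `coarse_rows` (indices violating the 2 km
#'   filter).
#' @export
genVirtualSpecies <- function(name, coefs, stacks, n_presences = 200L,
                              pre1950_fraction = 0.15, coarse_fraction = 0.1,
                              bias = NULL, seed = 1L) {
  set.seed(seed)
  truth_cur <- truthSuitability(stacks$current, coefs)
  truth_past <- truthSuitability(stacks$past, coefs)
  d <- dim(truth_cur)
  weight <- function(truth) {
    w <- as.vector(truth)
    if (!is.null(bias)) w <- w * as.vector(bias)
    w[is.na(w)] <- 0
    if (sum(w) <= 0) stop("truth suitability sums to zero")
    w
  }
  n_pre <- round(n_presences * pre1950_fraction)
  n_post <- n_presences - n_pre
  draw <- function(truth, n) {
    if (n == 0L) return(integer())
    sample.int(length(truth), n, replace = FALSE, prob = weight(truth))
  }
  cells_post <- draw(truth_cur, n_post)
  cells_pre <- draw(truth_past, n_pre)
  mk <- function(cells, years) {
    rc <- cbind((cells - 1L) %% d[1L] + 1L, (cells - 1L) %/% d[1L] + 1L)
    cc <- cellCenter(stacks$current, rc[, 1L], rc[, 2L])
    data.frame(species = name, lon = cc[, 1L], lat = cc[, 2L],
               year = years, precision_km = NA_real_, source = "synthetic")
  }
  rec <- rbind(
    if (n_pre) mk(cells_pre, sample(1900:1949, n_pre, replace = TRUE)),
    mk(cells_post, sample(1950:2000, n_post, replace = TRUE)))
  n <- nrow(rec)
  coarse <- sample.int(n, round(coarse_fraction * n))
  rec$precision_km <- stats::runif(n, 0.5, 2)
  rec$precision_km[coarse] <- stats::runif(length(coarse), 2.5, 10)
  list(truth = truth_cur, truth_past = truth_past, records = rec,
       coarse_rows = sort(coarse))
}

#' Expert rating emulated from truth/prediction overlap
#'
#' The Jaccard overlap of the predicted binary range with the
#' truth-thresholded range stands in for the expert's judgement:
#' >= 0.7 good, >= 0.4 medium, else poor.
#'
#' @param truth_binary,pred_binary binary matrices on one grid.
#' @return "good", "medium" or "poor".
#' @export
rateByOverlap <- function(truth_binary, pred_binary) {
  a <- truth_binary == 1L; b <- pred_binary == 1L
  a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE
  un <- sum(a | b)
  j <- if (un == 0L) 0 else sum(a & b) / un
  if (j >= 0.7) "good" else if (j >= 0.4) "medium" else "poor"
}

#' Simulate a tree, Brownian traits and a lambda-structured response
#'
#' Grows a pure-birth ultrametric phylogeny, simulates each predictor trait
#' by Brownian motion on it, and builds the response
#' `y = X beta_true + e` with `e ~ N(0, sigma^2 V(lambda_true))`, recording
#' the truth for recovery tests.
#'
#' @param n_tips number of species (>= 10).
#' @param birth_rate pure-birth speciation rate (default 1).
#' @param lambda_true Pagel's lambda of the response errors.
#' @param beta_true named coefficients over the simulated traits
#'   (default `c(x1 = 0.5, x2 = -0.3)`); an `(Intercept)` entry is allowed.
#' @param sigma residual standard deviation (default 1).
#' @param seed integer seed.
#' @return list: `tree`, `data` (species + traits + y), `truth` (the
#'   generating parameters).
#' @export
genComparative <- function(n_tips = 100L, birth_rate = 1, lambda_true = 1,
                           beta_true = c(x1 = 0.5, x2 = -0.3), sigma = 1,
                           seed = 1L) {
  stopifnot(n_tips >= 10L)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  V <- bmCovariance(tree)
  L <- t(chol(V))
  vars <- setdiff(names(beta_true), "(Intercept)")
  X <- vapply(vars, function(v) drop(L %*% stats::rnorm(n_tips)),
              numeric(n_tips))
  colnames(X) <- vars
  b0 <- if ("(Intercept)" %in% names(beta_true))
    beta_true[["(Intercept)"]] else 0
  Llam <- t(chol(lambdaTransform(V, lambda_true)))
  y <- b0 + drop(X %*% beta_true[vars]) +
    sigma * drop(Llam %*% stats::rnorm(n_tips))
  data <- data.frame(species = tree$tip.label, X, y = y,
                     row.names = NULL)
  list(tree = tree, data = data,
       truth = list(lambda = lambda_true, beta = beta_true, sigma = sigma))
}

#' Assemble the default synthetic study world
#'
#' Builds the full input set the pipeline needs: five-period climate stacks
#' (200 x 200 cells at 0.1 degree by default), terrain, and `n_species`
#' virtual species in three groups that mimic the pika / rabbit / hare
#' contrasts (cool narrow niches with small body mass through warm broad
#' niches with large mass), with per-species dispersal rates, traits and a
#' pure-birth phylogeny whose tips are the species.
#'
#' @param n_species total species count (default 12, split into 3 groups).
#' @param n_presences records per species (default 200).
#' @param dims,res grid geometry passed to [genClimate()].
#' @param shifts future shift specification passed to [genClimate()].
#' @param seed integer seed governing every draw.
#' @return list: `stacks`, `elevation`, `landcover`, `species` (data.frame
#'   of name, group, niche optimum, dispersal, hemisphere), `truth` (list of
#'   per-species truth rasters), `records` (all species pooled),
#'   `dispersal`, `traits`, `tree`.
#' @export
genWorld <- function(n_species = 12L, n_presences = 200L,
                     dims = c(200L, 200L), res = 0.1,
                     shifts = list(f2020s = list(offset = c(temp = 1)),
                                   f2050s = list(offset = c(temp = 2)),
                                   f2080s = list(offset = c(temp = 3))),
                     seed = 1L) {
  stacks <- genClimate(dims = dims, res = res, shifts = shifts, seed = seed)
  terr <- genTerrain(stacks$current, seed = seed + 1L)
  per_group <- ceiling(n_species / 3)
  groups <- rep(c("pikas", "rabbits", "hares"), each = per_group)[
    seq_len(n_species)]
  temp_cur <- getLayer(stacks$current, "temp")
  tr <- range(temp_cur)
  set.seed(seed + 2L)
  # group niches in distinct climate bands: pikas at the cool (poleward)
  # edge with the narrowest tolerance, hares warm with the broadest; a
  # second (precipitation) niche axis spreads congeners across longitude so
  # ranges are restricted blobs, not full-width bands, as in real
  # biogeography
  centre <- tr[1L] + c(pikas = 0.2, rabbits = 0.5, hares = 0.8) * diff(tr)
  opts <- stats::runif(n_species, centre[groups] - 1, centre[groups] + 1)
  widths <- ifelse(groups == "pikas", 0.8,
                   ifelse(groups == "rabbits", 1.0, 1.2))
  prec_cur <- getLayer(stacks$current, "prec")
  pr <- range(prec_cur)
  idx_in_group <- stats::ave(seq_len(n_species), groups, FUN = seq_along)
  prec_opts <- pr[1L] + (idx_in_group - 0.5) / per_group * diff(pr) +
    stats::runif(n_species, -1, 1)
  prec_widths <- ifelse(groups == "pikas", 1.8,
                        ifelse(groups == "rabbits", 2.2, 2.6))
  disp <- ifelse(groups == "pikas", stats::runif(n_species, 0.3, 0.6),
                 ifelse(groups == "rabbits", stats::runif(n_species, 0.8, 1.5),
                        stats::runif(n_species, 1.5, 3)))
  spnames <- sprintf("%s_%02d", groups, seq_len(n_species))
  species <- data.frame(species = spnames, group = groups, opt = opts,
                        width = widths, annual_km = disp, hemisphere = "N")
  truth <- list(); recs <- list()
  for (i in seq_len(n_species)) {
    ct <- gaussianNicheCoefs("temp", opts[i], widths[i], height = 3)
    cp <- gaussianNicheCoefs("prec", prec_opts[i], prec_widths[i],
                             height = 0)
    coefs <- c(ct[1L] + cp[1L], ct[-1L], cp[-1L])
    names(coefs)[1L] <- "(Intercept)"
    vs <- genVirtualSpecies(spnames[i], coefs,
                            stacks, n_presences = n_presences,
                            seed = seed + 10L + i)
    truth[[spnames[i]]] <- vs
    recs[[i]] <- vs$records
  }
  records <- do.call(rbind, recs)
  dispersal <- data.frame(species = spnames, annual_km = disp,
                          provenance = "observed")
  set.seed(seed + 3L)
  mass <- ifelse(groups == "pikas", stats::rlnorm(n_species, log(180), 0.2),
                 ifelse(groups == "rabbits",
                        stats::rlnorm(n_species, log(1300), 0.2),
                        stats::rlnorm(n_species, log(3200), 0.2)))
  traits <- data.frame(
    species = spnames,
    activity_cycle = sample(c("nocturnal", "diurnal", "flexible"),
                            n_species, replace = TRUE),
    body_mass_g = mass,
    diet_breadth = sample(1:8, n_species, replace = TRUE),
    gestation_days = round(stats::runif(n_species, 25, 42)),
    habitat_breadth = sample(1:4, n_species, replace = TRUE),
    home_range_km2 = stats::rlnorm(n_species, log(0.1), 1),
    litters_per_year = round(stats::runif(n_species, 1, 6)),
    litter_size = round(stats::runif(n_species, 1, 8)),
    population_density_per_km2 = stats::rlnorm(n_species, log(40), 1),
    sexual_maturity_days = round(stats::runif(n_species, 60, 400)))
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- sample(spnames)
  list(stacks = stacks, elevation = terr$elevation,
       landcover = terr$landcover, species = species, truth = truth,
       records = records, dispersal = dispersal, traits = traits,
       tree = tree)
}
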