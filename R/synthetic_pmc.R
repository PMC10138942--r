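# Seeded generator of synthetic pollen-mother-cell datasets. The
# generator emulates the statistical structure the analysis assumes —
# per-bivalent chiasma counts with an obligate-crossover constraint,
# Beta-distributed arm positions with tunable proximal/distal bias, and
# independent per-marker Poisson focus counts on separate slides — not
# the cytology itself.

PRESET_NAMES <- c("cepa_like", "fistulosum_like", "diploid_hybrid_like",
                  "triploid_hybrid_like")

#' Simulation configuration for a synthetic PMC sample
#'
#' Full parameterisation of one synthetic pollen-mother-cell population.
#'
#' @param sample_id sample label.
#' @param n_cells number of cells to simulate.
#' @param n_bivalents_per_cell bivalents per cell (default 8, the Allium
#'   haploid chromosome number).
#' @param chiasma_mean expected chiasmata per chiasmate bivalent; counts
#'   are drawn from a zero-truncated Poisson so every non-univalent
#'   bivalent carries at least one chiasma (the obligate crossover).
#' @param univalent_rate probability a bivalent forms no chiasma and
#'   appears as a univalent pair, in \[0, 1).
#' @param position_alpha,position_beta shape parameters of the Beta
#'   distribution of relative arm positions (alpha < beta biases
#'   proximal, alpha > beta distal).
#' @param interference_min_distance minimum allowed distance between two
#'   chiasmata on the same arm, in \[0, 0.5); 0 disables the rejection
#'   step.
#' @param foci_lambda_mlh1,foci_lambda_mus81 mean MLH1 / MUS81 foci per
#'   cell (Poisson).
#' @param n_cells_foci_per_marker cells scored per marker on each
#'   simulated slide.
#' @param seed integer seed; identical configurations (including the
#'   seed) give identical datasets.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(sample_id, n_cells,
                              n_bivalents_per_cell = 8,
                              chiasma_mean = 2,
                              univalent_rate = 0,
                              position_alpha = 1, position_beta = 1,
                              interference_min_distance = 0,
                              foci_lambda_mlh1 = 10,
                              foci_lambda_mus81 = 4,
                              n_cells_foci_per_marker = 40,
                              seed = 1L) {
  cfg <- list(sample_id = as.character(sample_id),
              n_cells = as.integer(n_cells),
              n_bivalents_per_cell = as.integer(n_bivalents_per_cell),
              chiasma_mean = as.numeric(chiasma_mean),
              univalent_rate = as.numeric(univalent_rate),
              position_alpha = as.numeric(position_alpha),
              position_beta = as.numeric(position_beta),
              interference_min_distance =
                as.numeric(interference_min_distance),
              foci_lambda_mlh1 = as.numeric(foci_lambda_mlh1),
              foci_lambda_mus81 = as.numeric(foci_lambda_mus81),
              n_cells_foci_per_marker = as.integer(n_cells_foci_per_marker),
              seed = as.integer(seed))
  ok <- cfg$n_cells >= 1 && cfg$n_bivalents_per_cell >= 1 &&
    cfg$chiasma_mean > 0 &&
    cfg$univalent_rate >= 0 && cfg$univalent_rate < 1 &&
    cfg$position_alpha > 0 && cfg$position_beta > 0 &&
    cfg$interference_min_distance >= 0 &&
    cfg$interference_min_distance < 0.5 &&
    cfg$foci_lambda_mlh1 >= 0 && cfg$foci_lambda_mus81 >= 0 &&
    cfg$n_cells_foci_per_marker >= 1 && !is.na(cfg$seed)
  if (!isTRUE(ok)) {
    abort_config("invalid simulation configuration (see ?simulation_config)")
  }
  structure(cfg, class = "simulation_config")
}

# lambda of a zero-truncated Poisson with the given truncated mean m > 1
ztp_lambda <- function(m) {
  if (m <= 1) {
    abort_config("zero-truncated Poisson mean must exceed 1")
  }
  uniroot(function(l) l / (1 - exp(-l)) - m,
          lower = 1e-10, upper = max(10, 2 * m), tol = 1e-12)$root
}

# exact zero-truncated Poisson sampler via the inverse-CDF trick
rztpois <- function(n, lambda) {
  qpois(runif(n, dpois(0, lambda), 1), lambda)
}

#' Calibrate Beta position parameters to target region proportions
#'
#' Finds Beta shape parameters whose analytic region proportions
#' `(F(lower), F(upper) - F(lower), 1 - F(upper))` (with `F` the Beta
#' CDF) match the target proportion triple, by Nelder-Mead search on the
#' log-parameters from a coarse grid of starting points.
#'
#' @param target_proportions three proportions summing to 1, each in
#'   (0, 1).
#' @param boundaries a [region_boundaries()] object.
#' @param tol squared-error tolerance (default `1e-4`); a warning is
#'   issued if only a worse fit is found.
#' @return named numeric vector `c(alpha =, beta =)`.
#' @examples
#' calibrate_beta(c(1, 1, 1) / 3) # about (1, 1): uniform
#' @export
calibrate_beta <- function(target_proportions,
                           boundaries = region_boundaries(),
                           tol = 1e-4) {
  t <- as.numeric(target_proportions)
  if (length(t) != 3 || any(t <= 0) || any(t >= 1) ||
      abs(sum(t) - 1) > 1e-6) {
    abort_config(
      "target proportions must be three values in (0, 1) summing to 1")
  }
  obj <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    p <- c(pbeta(boundaries$lower, a, b),
           pbeta(boundaries$upper, a, b) - pbeta(boundaries$lower, a, b),
           1 - pbeta(boundaries$upper, a, b))
    sum((p - t)^2)
  }
  best <- NULL
  for (a0 in c(0.2, 0.5, 1, 2, 5)) {
    for (b0 in c(0.2, 0.5, 1, 2, 5)) {
      fit <- optim(log(c(a0, b0)), obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (best$value > tol) {
    warning(sprintf(
      "calibrate_beta: best squared error %.3g exceeds tolerance %.3g",
      best$value, tol))
  }
  c(alpha = exp(best$par[1]), beta = exp(best$par[2]))
}

#' Analytic region proportions of a position distribution
#'
#' The probability mass a Beta(alpha, beta) position distribution assigns
#' to the proximal, interstitial and distal regions.
#'
#' @param config a [simulation_config()] (or any list with
#'   `position_alpha` and `position_beta`).
#' @param boundaries a [region_boundaries()] object.
#' @return named numeric triple summing to 1.
#' @export
region_proportions <- function(config, boundaries = region_boundaries()) {
  a <- config$position_alpha
  b <- config$position_beta
  p <- c(pbeta(boundaries$lower, a, b),
         pbeta(boundaries$upper, a, b) - pbeta(boundaries$lower, a, b),
         1 - pbeta(boundaries$upper, a, b))
  setNames(p, REGION_LEVELS)
}

#' Preset simulation configurations for the four Allium regimes
#'
#' Complete [simulation_config()]s emulating the four study regimes:
#' `cepa_like` (distal-localized), `fistulosum_like`
#' (proximal-localized), and the two hybrid regimes
#' (`diploid_hybrid_like`, `triploid_hybrid_like`). Beta position
#' parameters are calibrated so the analytic region proportions match the
#' reference regional percentages ([allium_chiasma_counts()]); the
#' chiasma mean is solved so the expected chiasma frequency per cell
#' matches the reference mean under the preset's univalent rate; focus
#' lambdas are the reference per-cell marker means
#' ([allium_foci_totals()]).
#'
#' @param name preset name.
#' @param seed integer seed stored in the returned configuration.
#' @return a [simulation_config()].
#' @examples
#' cfg <- pmc_preset("fistulosum_like", seed = 7)
#' region_proportions(cfg)
#' @export
pmc_preset <- function(name = PRESET_NAMES, seed = 1L) {
  name <- match.arg(name)
  sid <- switch(name,
                cepa_like = "cepa",
                fistulosum_like = "fistulosum",
                diploid_hybrid_like = "f1_diploid",
                triploid_hybrid_like = "f1_triploid")
  # univalent rates: cepa forms rings throughout; univalents and open
  # bivalents were seen in the other regimes, most often in the diploid
  # hybrid (homeologous pairing failure)
  uni <- c(cepa = 0, fistulosum = 0.02, f1_diploid = 0.05,
           f1_triploid = 0.02)[[sid]]
  cc <- allium_chiasma_counts()
  row <- cc[cc$sample_id == sid, ]
  total <- row$n_proximal + row$n_interstitial + row$n_distal
  shapes <- calibrate_beta(
    c(row$n_proximal, row$n_interstitial, row$n_distal) / total)
  mean_per_cell <- total / row$n_cells
  ztp_mean <- (mean_per_cell / 8) / (1 - uni)
  ft <- allium_foci_totals()
  ft <- ft[ft$sample_id == sid, ]
  lam <- setNames(ft$total_signals / ft$n_cells, ft$marker)
  simulation_config(
    sample_id = sid,
    n_cells = row$n_cells,
    n_bivalents_per_cell = 8,
    chiasma_mean = ztp_lambda(ztp_mean),
    univalent_rate = uni,
    position_alpha = shapes[["alpha"]],
    position_beta = shapes[["beta"]],
    interference_min_distance = 0,
    foci_lambda_mlh1 = lam[["MLH1"]],
    foci_lambda_mus81 = lam[["MUS81"]],
    n_cells_foci_per_marker = max(ft$n_cells),
    seed = seed)
}

# draw positions for one arm honouring the minimum-distance constraint;
# returns list(pos, flagged)
draw_arm_positions <- function(k, a, b, d, max_attempts = 100) {
  pos <- rbeta(k, a, b)
  if (k < 2 || d <= 0) return(list(pos = pos, flagged = FALSE))
  if (k * d >= 1) {
    abort_config(sprintf(
      "interference constraint impossible: %d chiasmata with min distance %.3g exceed arm capacity",
      k, d))
  }
  best <- pos
  best_sep <- min(diff(sort(pos)))
  attempt <- 1
  while (best_sep < d && attempt < max_attempts) {
    pos <- rbeta(k, a, b)
    sep <- min(diff(sort(pos)))
    if (sep > best_sep) {
      best <- pos
      best_sep <- sep
    }
    attempt <- attempt + 1
  }
  list(pos = best, flagged = best_sep < d)
}

#' Simulate chiasma and bivalent records for one sample
#'
#' Per bivalent: with probability `univalent_rate` the pair is emitted as
#' an achiasmate univalent pair; otherwise the chiasma count is drawn
#' from a zero-truncated Poisson (so every chiasmate bivalent has at
#' least one chiasma — the obligate crossover), each chiasma is assigned
#' uniformly to one of the two arms (arms are treated as equal length),
#' and relative positions are drawn from
#' Beta(`position_alpha`, `position_beta`). When
#' `interference_min_distance` > 0, positions on an arm are redrawn
#' (up to 100 attempts) until all same-arm distances meet the minimum;
#' if no attempt succeeds the best attempt is kept and the bivalent's
#' subtype is annotated with `" [interference-flagged]"`.
#'
#' The configuration's seed fully determines the output.
#'
#' @param config a [simulation_config()].
#' @param boundaries a [region_boundaries()] object used to annotate the
#'   derived bivalent table.
#' @return list with validated `chiasmata` and `bivalents` data.frames.
#' @export
simulate_chiasmata <- function(config, boundaries = region_boundaries()) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n_biv <- config$n_cells * config$n_bivalents_per_cell
  cell_id <- sprintf("c%03d", rep(seq_len(config$n_cells),
                                  each = config$n_bivalents_per_cell))
  biv_id <- sprintf("b%d", rep(seq_len(config$n_bivalents_per_cell),
                               times = config$n_cells))
  is_uni <- runif(n_biv) < config$univalent_rate
  k <- integer(n_biv)
  k[!is_uni] <- rztpois(sum(!is_uni), config$chiasma_mean)

  chi_rows <- vector("list", n_biv)
  subtype <- character(n_biv)
  configuration <- character(n_biv)
  for (i in seq_len(n_biv)) {
    if (k[i] == 0) {
      configuration[i] <- "univalent_pair"
      subtype[i] <- "univalent"
      next
    }
    arm <- sample(c(1L, 2L), k[i], replace = TRUE)
    pos <- numeric(k[i])
    flagged <- FALSE
    for (a in unique(arm)) {
      drawn <- draw_arm_positions(sum(arm == a), config$position_alpha,
                                  config$position_beta,
                                  config$interference_min_distance)
      pos[arm == a] <- drawn$pos
      flagged <- flagged || drawn$flagged
    }
    rec <- data.frame(sample_id = config$sample_id, cell_id = cell_id[i],
                      bivalent_id = biv_id[i], arm_id = arm, rel_pos = pos,
                      stringsAsFactors = FALSE)
    chi_rows[[i]] <- rec
    cls <- classify_bivalent(rec, boundaries)
    configuration[i] <- cls$configuration
    subtype[i] <- if (flagged)
      paste0(cls$subtype, " [interference-flagged]") else cls$subtype
  }
  chiasmata <- do.call(rbind, chi_rows[!vapply(chi_rows, is.null,
                                               logical(1))])
  if (is.null(chiasmata)) {
    chiasmata <- data.frame(sample_id = character(), cell_id = character(),
                            bivalent_id = character(), arm_id = integer(),
                            rel_pos = numeric(), stringsAsFactors = FALSE)
  }
  bivalents <- data.frame(sample_id = config$sample_id, cell_id = cell_id,
                          bivalent_id = biv_id,
                          is_univalent_pair = k == 0L,
                          chiasma_count = k,
                          configuration = configuration,
                          subtype = subtype,
                          stringsAsFactors = FALSE)
  list(chiasmata = validate_chiasma_records(chiasmata),
       bivalents = validate_bivalent_records(bivalents))
}

#' Simulate per-cell marker focus counts for one sample
#'
#' Emulates the separate-slide scoring design: `n_cells_foci_per_marker`
#' cells per marker, on distinct slides (`slide_MLH1`, `slide_MUS81`),
#' with counts drawn independently from Poisson distributions with the
#' configured per-marker means. Seeded and reproducible.
#'
#' @param config a [simulation_config()].
#' @return a validated focus-count data.frame.
#' @export
simulate_foci <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  # offset so focus counts are not coupled to the chiasma stream
  set.seed(config$seed + 1L)
  n <- config$n_cells_foci_per_marker
  rows <- lapply(FOCI_MARKERS, function(mk) {
    lam <- if (mk == "MLH1") config$foci_lambda_mlh1 else
      config$foci_lambda_mus81
    data.frame(sample_id = config$sample_id,
               slide_id = paste0("slide_", mk),
               cell_id = sprintf("fc%03d", seq_len(n)),
               marker = mk,
               count = rpois(n, lam),
               stringsAsFactors = FALSE)
  })
  validate_foci_records(do.call(rbind, rows))
}

#' Simulate a complete synthetic PMC dataset
#'
#' Runs [simulate_chiasmata()] and [simulate_foci()] for one or more
#' configurations and assembles the four standard tables.
#'
#' @param configs a [simulation_config()] or list of them (e.g. from
#'   [pmc_preset()]).
#' @param boundaries a [region_boundaries()] object.
#' @return list with `chiasmata`, `bivalents`, `foci` and `samples`
#'   data.frames.
#' @export
simulate_pmc_dataset <- function(configs, boundaries = region_boundaries()) {
  if (inherits(configs, "simulation_config")) configs <- list(configs)
  parts <- lapply(configs, function(cfg) {
    sim <- simulate_chiasmata(cfg, boundaries)
    sim$foci <- simulate_foci(cfg)
    sim$samples <- data.frame(
      sample_id = cfg$sample_id,
      display_label = cfg$sample_id,
      genome_composition = "synthetic",
      expected_bivalents_per_cell = cfg$n_bivalents_per_cell,
      stringsAsFactors = FALSE)
    sim
  })
  list(chiasmata = do.call(rbind, lapply(parts, `[[`, "chiasmata")),
       bivalents = do.call(rbind, lapply(parts, `[[`, "bivalents")),
       foci = do.call(rbind, lapply(parts, `[[`, "foci")),
       samples = validate_sample_records(
         do.call(rbind, lapply(parts, `[[`, "samples"))))
}
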