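#' Group template for the spectrum simulator
#'
#' Describes one biological group: peak masses, per-peak presence
#' probabilities and lognormal intensity parameters. Peaks shared by all
#' groups and group-enriched peaks are expressed through the
#' `presence_probs` vector of each group's template over a common mass set.
#'
#' @param label Group label.
#' @param peak_mzs Peak masses in Da, within the 2,000-20,000 Da window.
#' @param presence_probs Per-peak Bernoulli presence probability.
#' @param log_mean_intensity,log_sd Per-peak lognormal parameters of the
#'   raw peak height (log scale).
#' @return A list of class `group_template`.
#' @export
group_template <- function(label, peak_mzs, presence_probs,
                           log_mean_intensity, log_sd) {
  np <- length(peak_mzs)
  presence_probs <- rep_len(presence_probs, np)
  log_mean_intensity <- rep_len(log_mean_intensity, np)
  log_sd <- rep_len(log_sd, np)
  if (any(presence_probs < 0 | presence_probs > 1)) {
    abort("`presence_probs` must lie in [0, 1].")
  }
  ord <- order(peak_mzs)
  structure(list(label = as.character(label),
                 peak_mzs = as.numeric(peak_mzs[ord]),
                 presence_probs = presence_probs[ord],
                 log_mean_intensity = log_mean_intensity[ord],
                 log_sd = log_sd[ord]),
            class = "group_template")
}

#' Simulation configuration
#'
#' Bundles the group templates with the physical layer of the simulator:
#' Gaussian peak shapes on a uniform m/z grid, replicate-level mass jitter,
#' an exponentially decaying chemical baseline and additive Gaussian
#' detector noise (clipped at zero). Biological peak realisations
#' (presence and intensity) are drawn once per sample and shared by its
#' technical replicates.
#'
#' @param templates List of [group_template()]s, one per group.
#' @param n_samples Named integer vector of samples per group (names must
#'   match template labels).
#' @param n_replicates Technical replicates (spots) per sample, default 2.
#' @param peak_width_sigma Gaussian peak sigma in Da.
#' @param mass_jitter_sd Per-replicate, per-peak mass jitter sd in Da.
#' @param baseline_amplitude Baseline height at the low-mass edge
#'   (intensity units).
#' @param baseline_decay Exponential decay constant in Da.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param grid_step m/z grid step in Da.
#' @param mz_range Two-element mass window in Da.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(templates, n_samples, n_replicates = 2L,
                       peak_width_sigma = 5, mass_jitter_sd = 0.3,
                       baseline_amplitude = 5, baseline_decay = 3000,
                       noise_sd = 1, grid_step = 1,
                       mz_range = c(2000, 20000)) {
  labels <- vapply(templates, function(t) t$label, "")
  if (is.null(names(n_samples))) names(n_samples) <- labels
  if (!setequal(names(n_samples), labels)) {
    abort("`n_samples` names must match the template labels.")
  }
  if (any(n_samples < 2L)) abort("Need at least 2 samples per group.")
  if (any(c(peak_width_sigma, grid_step, baseline_decay) <= 0)) {
    abort("All simulator scales must be positive.")
  }
  if (noise_sd < 0 || mass_jitter_sd < 0 || baseline_amplitude < 0) {
    abort("`noise_sd`, `mass_jitter_sd` and `baseline_amplitude` must be >= 0.")
  }
  if (grid_step > peak_width_sigma) {
    abort("Grid too coarse to resolve the peak width; decrease `grid_step`.")
  }
  structure(list(templates = templates,
                 n_samples = setNames(as.integer(n_samples[labels]), labels),
                 n_replicates = as.integer(n_replicates),
                 peak_width_sigma = peak_width_sigma,
                 mass_jitter_sd = mass_jitter_sd,
                 baseline_amplitude = baseline_amplitude,
                 baseline_decay = baseline_decay,
                 noise_sd = noise_sd, grid_step = grid_step,
                 mz_range = as.numeric(mz_range)),
            class = "sim_config")
}

#' Default three-group configuration mirroring the study design
#'
#' 25 CTL, 22 IS and 29 LPS samples acquired in duplicate (152 spectra).
#' The common mass set holds 70 peaks between 2,200 and 19,400 Da: 40
#' shared peaks (presence 0.9 in every group) and 10 enriched peaks per
#' group (presence 0.9 in the enriched group, 0.2 elsewhere). Raw peak
#' heights are lognormal (median 25 counts for shared, 35 for enriched
#' peaks, sdlog 0.4); peaks are Gaussian with sigma 5 Da on a 1 Da grid,
#' jittered by 0.3 Da per replicate, over an exponential baseline
#' (amplitude 5 at 2 kDa, decay 3,000 Da) with unit Gaussian noise.
#'
#' @return A `sim_config`.
#' @export
default_paper_like_config <- function() {
  n_peaks <- 70L
  base <- seq(2200, 19400, length.out = n_peaks)
  # fixed irregular offsets so masses are not suspiciously equidistant
  offs <- withr::with_seed(20220706L, stats::runif(n_peaks, -40, 40))
  mzs <- sort(base + offs)
  slot <- (seq_len(n_peaks) - 1L) %% 7L   # 0..3 shared, 4/5/6 group-enriched
  shared <- slot <= 3L
  owner <- rep(NA_character_, n_peaks)
  owner[slot == 4L] <- "CTL"; owner[slot == 5L] <- "IS"; owner[slot == 6L] <- "LPS"
  log_mean <- ifelse(shared, log(25), log(35))
  make_tpl <- function(g) {
    p <- ifelse(shared, 0.9, ifelse(owner == g, 0.9, 0.2))
    group_template(g, mzs, p, log_mean, 0.4)
  }
  sim_config(templates = lapply(c("CTL", "IS", "LPS"), make_tpl),
             n_samples = c(CTL = 25L, IS = 22L, LPS = 29L))
}

#' Which default-template peaks are enriched in each group
#'
#' @param cfg A `sim_config` built like [default_paper_like_config()].
#' @return Tibble with `mz`, `group` (`NA` for shared peaks).
#' @export
template_truth <- function(cfg) {
  tpl <- cfg$templates
  labels <- vapply(tpl, function(t) t$label, "")
  probs <- sapply(tpl, function(t) t$presence_probs)
  owner <- apply(probs, 1, function(p) {
    hi <- p == max(p)
    if (all(hi)) NA_character_ else labels[which.max(p)]
  })
  tibble(mz = tpl[[1]]$peak_mzs, group = owner)
}

#' Generate a synthetic three-group spectrum dataset
#'
#' Per sample, peak presences (Bernoulli) and heights (lognormal) are
#' drawn once and shared by the sample's replicates; each replicate then
#' renders jittered Gaussian peaks over the exponential baseline plus
#' Gaussian noise, clipped at zero. Byte-identical given the same seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `spectra` (list of [raw_spectrum()]s), `manifest`
#'   (a `sample_manifest`), and `truth` (per-sample realised peak tibble:
#'   `sample_id`, `group`, `mz`, `present`, `intensity`).
#' @export
generate_dataset <- function(cfg, seed = 1L) {
  grid <- seq(cfg$mz_range[1], cfg$mz_range[2], by = cfg$grid_step)
  baseline <- cfg$baseline_amplitude *
    exp(-(grid - cfg$mz_range[1]) / cfg$baseline_decay)
  spectra <- list()
  truth <- list()
  man <- list()
  withr::with_seed(as.integer(seed), {
    for (tpl in cfg$templates) {
      g <- tpl$label
      for (s in seq_len(cfg$n_samples[[g]])) {
        sid <- sprintf("%s_%02d", g, s)
        present <- stats::rbinom(length(tpl$peak_mzs), 1, tpl$presence_probs)
        height <- stats::rlnorm(length(tpl$peak_mzs),
                                tpl$log_mean_intensity, tpl$log_sd) * present
        truth[[length(truth) + 1L]] <- tibble(
          sample_id = sid, group = g, mz = tpl$peak_mzs,
          present = as.integer(present), intensity = height)
        for (r in seq_len(cfg$n_replicates)) {
          sig <- baseline + render_peaks(grid, tpl$peak_mzs, height,
                                         cfg$peak_width_sigma,
                                         cfg$mass_jitter_sd)
          y <- pmax(sig + stats::rnorm(length(grid), 0, cfg$noise_sd), 0)
          spectra[[length(spectra) + 1L]] <-
            raw_spectrum(grid, y, sample_id = sid, group = g, replicate = r)
          man[[length(man) + 1L]] <- tibble(sample_id = sid, group = g,
                                            replicate = r)
        }
      }
    }
  })
  manifest <- validate_manifest(dplyr::bind_rows(man))
  list(spectra = spectra, manifest = manifest,
       truth = dplyr::bind_rows(truth))
}

# sum of Gaussian peaks, each evaluated only on its +/- 6 sigma support
render_peaks <- function(grid, mzs, heights, sigma, jitter_sd) {
  out <- numeric(length(grid))
  step <- grid[2] - grid[1]
  halfspan <- ceiling(6 * sigma / step)
  for (j in seq_along(mzs)) {
    if (heights[j] <= 0) next
    centre <- mzs[j] + if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
    ci <- round((centre - grid[1]) / step) + 1
    lo <- max(1L, ci - halfspan); hi <- min(length(grid), ci + halfspan)
    if (lo > hi) next
    idx <- lo:hi
    out[idx] <- out[idx] + heights[j] * exp(-(grid[idx] - centre)^2 / (2 * sigma^2))
  }
  out
}
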