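#' Configuration for the synthetic glycoproteomics generator
#'
#' Bundles and validates all parameters of [simulate_glyco_dataset()]. The
#' defaults emulate a wild-type embryonic O-glycoproteome: most glycosites
#' carry only Tn antigen (a single HexNAc), a minority carry both Tn and T
#' (HexHexNAc) glycoforms, most proteins have a single glycosite, and the
#' quantification noise on log10 mutant/control ratios is the scale whose
#' 3-sigma interval is +/-0.55.
#'
#' @param n_proteins number of glycoproteins to simulate.
#' @param sites_per_protein_dist probability vector over 1, 2, ... glycosites
#'   per protein. Default: 44% single-site, 20% two-site, geometric tail.
#' @param tn_only_prob,t_only_prob,both_prob per-site glycoform class
#'   probabilities; must sum to 1.
#' @param residue_probs probabilities for S/T/Y site residues (named vector).
#' @param null_sigma standard deviation of the log10 ratio under no change.
#' @param frac_changed fraction of glycosites given a true nonzero effect.
#' @param effect_log10 signed log10 effect magnitudes sampled uniformly for
#'   changed sites (e.g. `c(-1, 1)` for ten-fold shifts either way).
#' @param psm_per_site_dist probability vector over 1, 2, ... PSMs observed
#'   per site and glycoform.
#' @param singleton_rate probability that a record lacks its isotope partner
#'   and so carries exactly one channel intensity.
#' @param seed integer seed; the generator uses a private RNG stream.
#' @return an object of class `glyco_sim_config`.
#' @seealso [simulate_glyco_dataset()]
#' @export
glyco_sim_config <- function(n_proteins = 100,
                             sites_per_protein_dist = c(0.44, 0.20, 0.14, 0.09,
                                                        0.06, 0.04, 0.02, 0.01),
                             tn_only_prob = 0.77,
                             t_only_prob = 0.04,
                             both_prob = 0.19,
                             residue_probs = c(S = 0.212, T = 0.785, Y = 0.003),
                             null_sigma = 0.55 / 3,
                             frac_changed = 0.1,
                             effect_log10 = c(-1, 1),
                             psm_per_site_dist = c(0.5, 0.3, 0.2),
                             singleton_rate = 0.1,
                             seed = 1L) {
  if (!is_count(n_proteins)) stop_invalid("n_proteins must be a positive integer")
  probs <- c(tn_only_prob, t_only_prob, both_prob)
  if (!all(vapply(probs, is_prob, logical(1))) ||
      abs(sum(probs) - 1) > 1e-9) {
    stop_invalid("tn_only_prob, t_only_prob and both_prob must lie in [0,1] and sum to 1")
  }
  if (!is.numeric(residue_probs) || length(residue_probs) != 3L ||
      !identical(sort(names(residue_probs)), c("S", "T", "Y")) ||
      any(residue_probs < 0) || sum(residue_probs) <= 0) {
    stop_invalid("residue_probs must be a non-negative vector named S, T, Y")
  }
  if (!is.numeric(null_sigma) || length(null_sigma) != 1L || !is.finite(null_sigma) ||
      null_sigma <= 0) {
    stop_invalid("null_sigma must be > 0")
  }
  if (!is_prob(frac_changed)) stop_invalid("frac_changed must lie in [0,1]")
  if (!is.numeric(effect_log10) || length(effect_log10) < 1L ||
      any(!is.finite(effect_log10))) {
    stop_invalid("effect_log10 must be a non-empty vector of finite values")
  }
  if (!is_prob(singleton_rate)) stop_invalid("singleton_rate must lie in [0,1]")
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    sites_per_protein_dist = sites_per_protein_dist,
    tn_only_prob = tn_only_prob, t_only_prob = t_only_prob,
    both_prob = both_prob,
    residue_probs = residue_probs[c("S", "T", "Y")],
    null_sigma = null_sigma, frac_changed = frac_changed,
    effect_log10 = effect_log10,
    psm_per_site_dist = psm_per_site_dist,
    singleton_rate = singleton_rate, seed = as.integer(seed)
  )
  # validate the distribution vectors eagerly
  discrete_sampler(sites_per_protein_dist)
  discrete_sampler(psm_per_site_dist)
  structure(cfg, class = "glyco_sim_config")
}

#' Simulate flow-through peptide log10 ratios under the null
#'
#' Draws the log10 medium/light (control/mutant) ratios of non-glycosylated
#' peptides that pass through the lectin column unretained. These peptides
#' carry no differential glycosylation signal, so their ratios form the
#' empirical null used to calibrate the candidate cutoff: a zero-centred
#' normal whose scale reflects labelling and measurement noise.
#'
#' @param n number of peptide ratios to draw.
#' @param sigma standard deviation of the log10 ratio null.
#' @param seed integer seed (private RNG stream).
#' @return numeric vector of `n` log10 ratios.
#' @examples
#' r <- simulate_flowthrough_ratios(1000, sigma = 0.55 / 3, seed = 1)
#' mean(abs(r) <= 0.55)  # close to 0.9973
#' @export
simulate_flowthrough_ratios <- function(n, sigma, seed = 1L) {
  if (!is_count(n)) stop_invalid("n must be a positive integer")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop_invalid("sigma must be > 0")
  }
  with_local_seed(seed, stats::rnorm(n, mean = 0, sd = sigma))
}

#' Simulate a glycopeptide quantification table with ground truth
#'
#' Generates one row per peptide-spectrum match (PSM) with the schema consumed
#' by the glyco pipeline, plus a separate ground-truth table giving every
#' site's true log10 effect and glycoform class. Channel intensities are
#' log-normal; the light (mutant) channel equals the medium (control) channel
#' times `10^(true effect + noise)`, so the PSM log ratio is the true effect
#' plus null noise. With probability `singleton_rate` a record loses one
#' channel at random and becomes an unpairable singleton.
#'
#' @param config a [glyco_sim_config()].
#' @return list with elements `records` (data.frame of GlycopeptideRecord
#'   rows: protein_id, peptide, site_position, residue, glycoform,
#'   intensity_medium, intensity_light, paired) and `truth` (data.frame:
#'   protein_id, site_position, residue, glycoform_class, true_effect,
#'   changed).
#' @export
simulate_glyco_dataset <- function(config) {
  if (!inherits(config, "glyco_sim_config")) {
    stop_invalid("config must be created with glyco_sim_config()")
  }
  with_local_seed(config$seed, {
    site_sampler <- discrete_sampler(config$sites_per_protein_dist)
    psm_sampler <- discrete_sampler(config$psm_per_site_dist)

    n_sites_per_prot <- site_sampler(config$n_proteins)
    protein_ids <- sprintf("P%04d", seq_len(config$n_proteins))

    prot <- rep(protein_ids, n_sites_per_prot)
    n_sites <- length(prot)
    # distinct positions within each protein
    pos <- unlist(lapply(n_sites_per_prot, function(k) {
      sort(sample.int(500L, k))
    }), use.names = FALSE)
    residue <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                      prob = config$residue_probs)
    klass <- sample(c("Tn-only", "T-only", "both"), n_sites, replace = TRUE,
                    prob = c(config$tn_only_prob, config$t_only_prob,
                             config$both_prob))
    changed <- stats::runif(n_sites) < config$frac_changed
    effect <- ifelse(
      changed,
      sample(config$effect_log10, n_sites, replace = TRUE),
      0
    )

    truth <- data.frame(
      protein_id = prot, site_position = pos, residue = residue,
      glycoform_class = klass, true_effect = effect, changed = changed,
      stringsAsFactors = FALSE
    )

    rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      forms <- switch(truth$glycoform_class[i],
                      "Tn-only" = "Tn", "T-only" = "T", both = c("Tn", "T"))
      site_rows <- lapply(forms, function(gf) {
        n_psm <- psm_sampler(1L)
        base <- 10 ^ stats::rnorm(n_psm, mean = 5, sd = 0.5)
        ratio <- truth$true_effect[i] +
          stats::rnorm(n_psm, sd = config$null_sigma)
        medium <- base
        light <- base * 10 ^ ratio
        singleton <- stats::runif(n_psm) < config$singleton_rate
        drop_light <- singleton & (stats::runif(n_psm) < 0.5)
        drop_medium <- singleton & !drop_light
        light[drop_light] <- NA_real_
        medium[drop_medium] <- NA_real_
        data.frame(
          protein_id = truth$protein_id[i],
          peptide = random_peptide(truth$residue[i]),
          site_position = truth$site_position[i],
          residue = truth$residue[i],
          glycoform = gf,
          intensity_medium = medium,
          intensity_light = light,
          paired = !singleton,
          stringsAsFactors = FALSE
        )
      })
      rows[[i]] <- do.call(rbind, site_rows)
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    list(records = records, truth = truth)
  })
}

# Plausible tryptic peptide string containing the glycosylated residue.
random_peptide <- function(residue) {
  aa <- c("A", "G", "L", "V", "P", "E", "D", "N", "Q", "F")
  len <- sample(7:12, 1L)
  p <- sample(aa, len, replace = TRUE)
  p[sample.int(len - 1L, 1L)] <- residue
  p[len] <- sample(c("K", "R"), 1L)
  paste(p, collapse = "")
}

#' Configuration for the persistent-random-walk track generator
#'
#' @param n_tracks number of tracks.
#' @param n_frames number of time points per track (at least 2).
#' @param dt frame interval in seconds (default 40, the acquisition rate of
#'   the two-photon movies the metrics were designed for).
#' @param speed cell speed in micrometres per minute; every step has length
#'   `speed * dt / 60`.
#' @param persistence directional correlation in `[0, 1)`: 0 gives an
#'   isotropic random walk, values near 1 give nearly straight paths.
#' @param seed integer seed.
#' @return an object of class `track_sim_config`.
#' @export
track_sim_config <- function(n_tracks = 10, n_frames = 60, dt = 40,
                             speed = 2.46, persistence = 0.5, seed = 1L) {
  if (!is_count(n_tracks)) stop_invalid("n_tracks must be a positive integer")
  if (!is_count(n_frames) || n_frames < 2) {
    stop_invalid("n_frames must be an integer >= 2")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop_invalid("dt must be > 0")
  }
  if (!is.numeric(speed) || length(speed) != 1L || !is.finite(speed) || speed < 0) {
    stop_invalid("speed must be >= 0")
  }
  if (!is.numeric(persistence) || length(persistence) != 1L ||
      !is.finite(persistence) || persistence < 0 || persistence >= 1) {
    stop_invalid("persistence must lie in [0, 1)")
  }
  structure(
    list(n_tracks = as.integer(n_tracks), n_frames = as.integer(n_frames),
         dt = dt, speed = speed, persistence = persistence,
         seed = as.integer(seed)),
    class = "track_sim_config"
  )
}

#' Simulate 3D nuclei tracks as a persistent random walk
#'
#' Fixed-step-length persistent random walk in 3D: every step has length
#' `speed * dt / 60` micrometres, and each new heading is the unit vector of
#' `persistence * previous_heading + (1 - persistence) * random_unit_vector`.
#' In the `persistence -> 1` limit the path is a straight line; at
#' `persistence = 0` headings are independent and isotropic. Speed and
#' directionality ground truth are therefore both exposed.
#'
#' @param config a [track_sim_config()].
#' @return list of [track()] objects.
#' @export
simulate_tracks <- function(config) {
  if (!inherits(config, "track_sim_config")) {
    stop_invalid("config must be created with track_sim_config()")
  }
  step_len <- config$speed * config$dt / 60
  with_local_seed(config$seed, {
    lapply(seq_len(config$n_tracks), function(id) {
      n_steps <- config$n_frames - 1L
      pos <- matrix(0, nrow = config$n_frames, ncol = 3L)
      pos[1L, ] <- stats::runif(3L, 0, 100)
      heading <- random_unit3(1L)[1L, ]
      for (s in seq_len(n_steps)) {
        perturb <- random_unit3(1L)[1L, ]
        h <- config$persistence * heading +
          (1 - config$persistence) * perturb
        nrm <- sqrt(sum(h^2))
        if (nrm < .Machine$double.eps) h <- perturb else h <- h / nrm
        heading <- h
        pos[s + 1L, ] <- pos[s, ] + step_len * heading
      }
      track(
        track_id = sprintf("track%03d", id),
        frames = seq_len(config$n_frames) - 1L,
        times = (seq_len(config$n_frames) - 1L) * config$dt,
        positions = pos
      )
    })
  })
}

# n uniformly distributed 3D unit vectors (rows).
random_unit3 <- function(n) {
  m <- matrix(stats::rnorm(3L * n), ncol = 3L)
  m / sqrt(rowSums(m^2))
}

#' Simulate a two-channel image pair with a target Pearson correlation
#'
#' Builds two Gaussian-noise grayscale rasters whose pixelwise Pearson
#' correlation converges to `rho` as the pixel count grows: channel B is
#' `rho * A + sqrt(1 - rho^2) * independent noise`, shifted to non-negative
#' intensities. At `rho = 1` the channels are equal up to an affine map.
#'
#' @param height,width raster dimensions in pixels.
#' @param rho target correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @return an [image_pair()] with channels `channel_a`, `channel_b`.
#' @export
simulate_image_pair <- function(height, width, rho, seed = 1L) {
  if (!is_count(height) || !is_count(width)) {
    stop_invalid("height and width must be positive integers")
  }
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) > 1) {
    stop_invalid("rho must lie in [-1, 1]")
  }
  with_local_seed(seed, {
    a <- matrix(stats::rnorm(height * width), nrow = height)
    noise <- matrix(stats::rnorm(height * width), nrow = height)
    b <- rho * a + sqrt(1 - rho^2) * noise
    # shift/scale to a non-negative 12-bit-like intensity range; Pearson is
    # invariant under these affine maps
    image_pair(channel_a = 500 + 100 * a, channel_b = 500 + 100 * b)
  })
}
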