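#' Generate labeled Grassmann class clouds
#'
#' Draws K prototype subspaces and perturbs each to produce class
#' members: a member is `orthonormalize(prototype + noise * G)` with G
#' a standard Gaussian D x p matrix, so `noise` scales the spread of a
#' class around its prototype on the manifold (noise 0 reproduces the
#' prototype exactly). Prototypes are redrawn until every pair is at
#' least `prototype_separation` apart in projection distance; when the
#' requested separation is the metric's maximum p (and K*p <= D), the
#' prototypes are instead built mutually orthogonal from one random
#' orthonormal frame, since random redraws cannot hit the maximum
#' exactly.
#'
#' @param K Number of classes (default 3).
#' @param n_per_class Members per class (default 30).
#' @param D,p Ambient and subspace dimension (defaults 40 and 5).
#' @param noise Perturbation scale sigma >= 0 (default 0.1).
#' @param prototype_separation Minimum pairwise projection distance
#'   between prototypes (default `p/2`).
#' @param seed Integer seed; the output is deterministic per seed.
#' @param max_tries Redraw budget before declaring the separation
#'   infeasible (default 200).
#' @return A [grassmann_set()] with classes `class_1 ... class_K`.
#' @export
gen_grassmann_classes <- function(K = 3L, n_per_class = 30L, D = 40L,
                                  p = 5L, noise = 0.1,
                                  prototype_separation = p / 2,
                                  seed = NULL, max_tries = 200L) {
  stopifnot(K >= 1L, n_per_class >= 1L, p >= 1L, p <= D, noise >= 0,
            prototype_separation >= 0)
  with_local_seed(seed, {
    protos <- NULL
    if (prototype_separation >= p * (1 - 1e-9)) {
      if (K * p > D) {
        stop("separation ", prototype_separation, " infeasible: ",
             "mutually orthogonal prototypes need K*p <= D",
             call. = FALSE)
      }
      frame <- random_orthonormal(D, K * p)
      protos <- lapply(seq_len(K), function(k) {
        grassmann_point(frame[, ((k - 1L) * p + 1L):(k * p),
                              drop = FALSE], check = FALSE)
      })
    } else {
      for (try in seq_len(max_tries)) {
        cand <- lapply(seq_len(K), function(k) {
          grassmann_point(random_orthonormal(D, p), check = FALSE)
        })
        ok <- TRUE
        if (K > 1L) {
          for (a in 1:(K - 1L)) {
            for (b in (a + 1L):K) {
              if (projection_distance(cand[[a]], cand[[b]]) <
                    prototype_separation) {
                ok <- FALSE
                break
              }
            }
            if (!ok) break
          }
        }
        if (ok) {
          protos <- cand
          break
        }
      }
      if (is.null(protos)) {
        stop("could not draw ", K, " prototypes with pairwise ",
             "separation >= ", prototype_separation, " on G(", p, ",",
             D, ") in ", max_tries, " tries", call. = FALSE)
      }
    }
    pts <- list()
    labs <- character(0)
    for (k in seq_len(K)) {
      for (i in seq_len(n_per_class)) {
        pert <- protos[[k]]$basis + noise * matrix(stats::rnorm(D * p), D, p)
        pts[[length(pts) + 1L]] <-
          grassmann_point(orthonormalize(pert)$Q, check = FALSE)
        labs <- c(labs, paste0("class_", k))
      }
    }
    out <- grassmann_set(pts, labs)
    attr(out, "prototypes") <- protos
    out
  })
}

#' Default five-class synthetic EEG class specifications
#'
#' A Bonn-shaped synthetic population: five classes with disjoint
#' dominant frequency bands, and a seizure analogue (`E`) with strong
#' low-frequency rhythm, high-amplitude Poisson-timed biphasic spikes
#' and extra noise. Amplitudes are on an integer-ADC-like scale (tens
#' of units) so the signals survive rounding to integer Bonn-layout
#' files.
#'
#' @param noise_sd Common Gaussian noise standard deviation (default
#'   5).
#' @return Named list (classes `A`-`E`) of class specifications
#'   consumable by [gen_synthetic_eeg()].
#' @export
default_eeg_classes <- function(noise_sd = 5) {
  list(
    A = list(bands = list(list(freq = c(8, 13), power = 400)),
             spike_rate = 0, spike_amp = 0, noise_sd = noise_sd),
    B = list(bands = list(list(freq = c(15, 20), power = 400)),
             spike_rate = 0, spike_amp = 0, noise_sd = noise_sd),
    C = list(bands = list(list(freq = c(25, 32), power = 400)),
             spike_rate = 0, spike_amp = 0, noise_sd = noise_sd),
    D = list(bands = list(list(freq = c(38, 48), power = 400)),
             spike_rate = 0, spike_amp = 0, noise_sd = noise_sd),
    E = list(bands = list(list(freq = c(3, 7), power = 1600)),
             spike_rate = 5, spike_amp = 150, noise_sd = 2 * noise_sd)
  )
}

# One biphasic spike (derivative-of-Gaussian shape), centred, ~0.12 s.
spike_pulse <- function(sampling_rate, amp, width_s = 0.02) {
  half <- round(3 * width_s * sampling_rate)
  t <- (-half:half) / sampling_rate
  w <- -t / width_s * exp(0.5 - t^2 / (2 * width_s^2))
  amp * w
}

#' Generate Bonn-like synthetic EEG segments
#'
#' Each segment is a sum of band-limited oscillations (a fixed number
#' of sinusoidal components with frequencies drawn uniformly in the
#' band and uniform random phases, scaled so the band contributes its
#' specified mean power), Gaussian noise, and an optional
#' Poisson-timed biphasic spike train (the ictal analogue). Not a
#' physiological EEG model: the classes are spectral caricatures with
#' Bonn-like shape, built so class structure is controllable.
#'
#' @param classes Named list of class specs: each has `bands` (list of
#'   `list(freq = c(lo, hi), power = ...)`), `spike_rate` (spikes/s),
#'   `spike_amp`, `noise_sd`. See [default_eeg_classes()].
#' @param n_per_class Segments per class (default 10).
#' @param length_samples Samples per segment (default 4097, the Bonn
#'   segment length: 23.6 s at 173.61 Hz).
#' @param sampling_rate Hz (default 173.61).
#' @param components Sinusoids per band (default 8).
#' @param seed Integer seed; deterministic per seed.
#' @return List of [eeg_segment()]s (class `eeg_segment_list`),
#'   labeled by class name.
#' @export
gen_synthetic_eeg <- function(classes = default_eeg_classes(),
                              n_per_class = 10L, length_samples = 4097L,
                              sampling_rate = 173.61, components = 8L,
                              seed = NULL) {
  stopifnot(length(classes) >= 1L, n_per_class >= 1L,
            length_samples >= 2L, sampling_rate > 0)
  nyq <- sampling_rate / 2
  for (nm in names(classes)) {
    for (b in classes[[nm]]$bands) {
      if (max(b$freq) >= nyq) {
        stop("class ", nm, ": band [", b$freq[1], ",", b$freq[2],
             "] Hz exceeds the Nyquist frequency ", nyq, " Hz",
             call. = FALSE)
      }
    }
  }
  tt <- (seq_len(length_samples) - 1) / sampling_rate
  dur <- length_samples / sampling_rate
  with_local_seed(seed, {
    segs <- list()
    for (nm in names(classes)) {
      spec <- classes[[nm]]
      for (i in seq_len(n_per_class)) {
        x <- numeric(length_samples)
        for (b in spec$bands) {
          fr <- stats::runif(components, b$freq[1], b$freq[2])
          ph <- stats::runif(components, 0, 2 * pi)
          amp <- sqrt(2 * b$power / components)
          for (j in seq_len(components)) {
            x <- x + amp * sin(2 * pi * fr[j] * tt + ph[j])
          }
        }
        if (isTRUE(spec$spike_rate > 0) && spec$spike_amp > 0) {
          nsp <- stats::rpois(1, spec$spike_rate * dur)
          if (nsp > 0) {
            pulse <- spike_pulse(sampling_rate, spec$spike_amp)
            half <- (length(pulse) - 1L) %/% 2L
            centers <- round(stats::runif(nsp, half + 1,
                                          length_samples - half))
            for (ct in centers) {
              idx <- (ct - half):(ct + half)
              x[idx] <- x[idx] + pulse
            }
          }
        }
        if (spec$noise_sd > 0) {
          x <- x + stats::rnorm(length_samples, 0, spec$noise_sd)
        }
        segs[[length(segs) + 1L]] <- eeg_segment(
          x, sampling_rate = sampling_rate, label = nm,
          source_id = sprintf("%s%03d", nm, i))
      }
    }
    structure(segs, class = "eeg_segment_list")
  })
}

#' Write segments as a Bonn-layout ASCII archive
#'
#' Creates the five-folder directory structure of the Bonn archive
#' (`Z/O/N/F/S` for groups A-E) with one plain-text file per segment,
#' one integer sample per line, so that [read_bonn_directory()] can be
#' exercised on synthetic data.
#'
#' @param segments List of [eeg_segment()]s with labels in `A`-`E`.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_bonn_layout <- function(segments, root) {
  rev_map <- stats::setNames(names(bonn_folder_map), bonn_folder_map)
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  counts <- integer(0)
  for (seg in segments) {
    if (!seg$label %in% names(rev_map)) {
      stop("segment label '", seg$label,
           "' is not a Bonn group (A-E)", call. = FALSE)
    }
    folder <- rev_map[[seg$label]]
    dir.create(file.path(root, folder), showWarnings = FALSE)
    counts[folder] <- (if (is.na(counts[folder])) 0L else counts[folder]) + 1L
    fn <- file.path(root, folder,
                    sprintf("%s%03d.txt", folder, counts[folder]))
    writeLines(as.character(round(seg$samples)), fn)
  }
  invisible(root)
}
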