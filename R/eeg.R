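#' Construct a single-channel EEG segment
#'
#' @param samples Numeric vector of amplitudes (arbitrary ADC units).
#' @param sampling_rate Sampling rate in Hz; the Bonn archive uses
#'   173.61 Hz.
#' @param label Group label, one of `"A"`–`"E"` (or any string for user
#'   data).
#' @param source_id Identifier (file stem) carried through the pipeline
#'   for error reporting.
#' @return Object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, sampling_rate = 173.61, label = NA_character_,
                        source_id = NA_character_) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("EEG samples must be finite", call. = FALSE)
  }
  stopifnot(sampling_rate > 0, length(samples) >= 1L)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         label = as.character(label), source_id = as.character(source_id)),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat("<eeg_segment>", x$source_id, "group", x$label, "-",
      length(x$samples), "samples @", x$sampling_rate, "Hz\n")
  invisible(x)
}

# Bonn archive folder naming: Z (healthy, eyes open) -> A,
# O (healthy, eyes closed) -> B, N (interictal, opposite hemisphere)
# -> C, F (interictal, epileptogenic zone) -> D, S (ictal) -> E.
bonn_folder_map <- c(Z = "A", O = "B", N = "C", F = "D", S = "E")

#' Read a Bonn-style EEG archive directory
#'
#' Expects the layout of the University of Bonn EEG archive: one
#' subfolder per group, named `Z/O/N/F/S` (mapped to group labels
#' `A/B/C/D/E`) or directly `A`–`E`, each holding plain ASCII files
#' with one sample per line (the Bonn files are 4097-sample integer
#' series, 23.6 s at 173.61 Hz).
#'
#' @param root Directory containing the group subfolders.
#' @param groups Group labels to load (default all of `A`–`E`). A
#'   mapped folder missing for a requested group is an error.
#' @param sampling_rate Sampling rate attached to every segment
#'   (default 173.61 Hz).
#' @return List of [eeg_segment()]s (class `eeg_segment_list`).
#' @export
read_bonn_directory <- function(root, groups = c("A", "B", "C", "D", "E"),
                                sampling_rate = 173.61) {
  if (!dir.exists(root)) {
    stop("directory not found: ", root, call. = FALSE)
  }
  groups <- match.arg(groups, several.ok = TRUE)
  segs <- list()
  for (g in groups) {
    folder_names <- c(names(bonn_folder_map)[bonn_folder_map == g], g)
    hit <- folder_names[dir.exists(file.path(root, folder_names))]
    if (length(hit) == 0L) {
      stop("missing group folder for group ", g, " (looked for ",
           paste(folder_names, collapse = " or "), " under ", root, ")",
           call. = FALSE)
    }
    dirpath <- file.path(root, hit[1L])
    files <- sort(list.files(dirpath, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) {
      stop("no data files in group folder ", dirpath, call. = FALSE)
    }
    for (f in files) {
      vals <- tryCatch(
        scan(f, what = numeric(), quiet = TRUE),
        error = function(e) {
          stop("parse error in ", f, ": ", conditionMessage(e),
               call. = FALSE)
        }
      )
      if (length(vals) == 0L) {
        stop("empty data file: ", f, call. = FALSE)
      }
      segs[[length(segs) + 1L]] <- eeg_segment(
        vals, sampling_rate = sampling_rate, label = g,
        source_id = sub("\\.[^.]*$", "", basename(f))
      )
    }
  }
  if (length(segs) == 0L) {
    stop("no EEG segments found under ", root, call. = FALSE)
  }
  structure(segs, class = "eeg_segment_list")
}

#' Split a segment into fixed-length sub-epochs
#'
#' Tiling that turns one recording into the "frames" of an image set:
#' windows `[i*hop, i*hop + subepoch_len)` for i = 0, 1, ..., as many
#' as fit; any trailing remainder is dropped.
#'
#' @param segment An [eeg_segment()] or a numeric vector.
#' @param subepoch_len Window length in samples (default 512,
#'   about 2.95 s at the Bonn rate).
#' @param hop Hop between window starts in samples (default 512, i.e.
#'   non-overlapping).
#' @return List of numeric vectors, each of length `subepoch_len`.
#' @export
split_subepochs <- function(segment, subepoch_len = 512L, hop = 512L) {
  x <- if (inherits(segment, "eeg_segment")) segment$samples else
    as.numeric(segment)
  n <- length(x)
  subepoch_len <- as.integer(subepoch_len)
  hop <- as.integer(hop)
  stopifnot(hop >= 1L)
  if (subepoch_len > n) {
    stop("segment too short: ", n, " samples < subepoch_len ",
         subepoch_len, call. = FALSE)
  }
  nw <- (n - subepoch_len) %/% hop + 1L
  lapply(seq_len(nw) - 1L, function(i) x[(i * hop + 1L):(i * hop + subepoch_len)])
}

#' Log-power STFT spectrogram of one sub-epoch
#'
#' Short-time Fourier transform with a Hann taper: frames of
#' `stft_window` samples advance by `stft_window - stft_overlap`; each
#' frame is zero-padded to `fft_size`, and the one-sided
#' magnitude-squared spectrum (`fft_size/2 + 1` bins for real input) is
#' passed through `log(power + eps)` so that zero power stays finite.
#'
#' @param window Numeric vector (one sub-epoch).
#' @param sampling_rate Hz.
#' @param stft_window Frame length in samples (default 128).
#' @param stft_overlap Overlap between consecutive frames in samples
#'   (default 64); must be smaller than `stft_window`.
#' @param fft_size FFT length (default 128; >= `stft_window`).
#' @param eps Additive floor inside the log (default `1e-12`).
#' @return Object of class `spectrogram`: `values` (m frames x n bins
#'   log-power matrix), `frame_times` (s, frame centres), `freqs` (Hz).
#' @export
log_spectrogram <- function(window, sampling_rate,
                            stft_window = 128L, stft_overlap = 64L,
                            fft_size = 128L, eps = 1e-12) {
  x <- as.numeric(window)
  stft_window <- as.integer(stft_window)
  stft_overlap <- as.integer(stft_overlap)
  fft_size <- as.integer(fft_size)
  stopifnot(stft_overlap >= 0L, stft_overlap < stft_window,
            stft_window <= length(x), fft_size >= stft_window,
            sampling_rate > 0)
  if (all(x == 0)) {
    warning("all-zero input window: spectrogram is the log-eps floor",
            call. = FALSE)
  }
  hop <- stft_window - stft_overlap
  starts <- seq.int(1L, length(x) - stft_window + 1L, by = hop)
  taper <- signal::hanning(stft_window)
  frames <- vapply(starts, function(s) {
    fr <- x[s:(s + stft_window - 1L)] * taper
    c(fr, numeric(fft_size - stft_window))
  }, numeric(fft_size))
  spec <- stats::mvfft(frames)              # fft_size x m
  nb <- fft_size %/% 2L + 1L
  power <- Mod(spec[seq_len(nb), , drop = FALSE])^2
  values <- t(log(power + eps))             # m frames x n bins
  structure(
    list(
      values = values,
      frame_times = (starts - 1 + stft_window / 2) / sampling_rate,
      freqs = (seq_len(nb) - 1) * sampling_rate / fft_size
    ),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat("<spectrogram>", nrow(x$values), "frames x", ncol(x$values),
      "frequency bins (", format(min(x$freqs), digits = 4), "-",
      format(max(x$freqs), digits = 4), "Hz )\n")
  invisible(x)
}

# Block-average a matrix down to m2 x n2 using near-equal index bins.
block_average <- function(mat, m2, n2) {
  stopifnot(m2 >= 1L, n2 >= 1L, m2 <= nrow(mat), n2 <= ncol(mat))
  rg <- as.integer(cut(seq_len(nrow(mat)), m2, labels = FALSE))
  cg <- as.integer(cut(seq_len(ncol(mat)), n2, labels = FALSE))
  out <- matrix(0, m2, n2)
  cnt <- matrix(0, m2, n2)
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      out[rg[i], cg[j]] <- out[rg[i], cg[j]] + mat[i, j]
      cnt[rg[i], cg[j]] <- cnt[rg[i], cg[j]] + 1
    }
  }
  out / cnt
}

#' Embed a set of spectrograms as one Grassmann point
#'
#' Vectorizes each of the M spectrograms column-major, stacks them as
#' the columns of \eqn{Y = [vec(X_1), ..., vec(X_M)]}, takes the SVD
#' \eqn{Y = U \Sigma V^T}, and returns the first p columns of U as a
#' point of \eqn{\mathcal{G}(p, m n)}. Column signs are fixed so the
#' largest-magnitude entry of each basis column is positive, making the
#' embedding deterministic.
#'
#' @param spectrograms List of [log_spectrogram()] outputs (or plain
#'   matrices) of identical shape.
#' @param p Subspace dimension (default 5); must not exceed the
#'   numerical rank of Y.
#' @param resize Optional `c(m2, n2)`: block-average every spectrogram
#'   down to m2 x n2 before vectorization (reins in the ambient
#'   dimension for finer STFT settings). Default `NULL` (off).
#' @return A [grassmann_point()] with ambient dimension m*n (after any
#'   resize).
#' @export
embed_spectrum_set <- function(spectrograms, p = 5L, resize = NULL) {
  stopifnot(is.list(spectrograms), length(spectrograms) >= 1L)
  mats <- lapply(spectrograms, function(s) {
    m <- if (inherits(s, "spectrogram")) s$values else as.matrix(s)
    if (!all(is.finite(m))) stop("non-finite spectrogram", call. = FALSE)
    m
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all spectrograms must share one shape", call. = FALSE)
  }
  if (!is.null(resize)) {
    mats <- lapply(mats, block_average, m2 = resize[1L], n2 = resize[2L])
  }
  Y <- vapply(mats, as.vector, numeric(length(mats[[1L]])))
  Y <- as.matrix(Y)
  sv <- svd(Y)
  rnk <- sum(sv$d > max(dim(Y)) * .Machine$double.eps * max(sv$d, 0))
  if (p > rnk) {
    stop("subspace dimension p = ", p, " exceeds numerical rank ", rnk,
         " of the stacked spectrum set", call. = FALSE)
  }
  U <- sv$u[, seq_len(p), drop = FALSE]
  for (j in seq_len(ncol(U))) {
    piv <- which.max(abs(U[, j]))
    if (U[piv, j] < 0) U[, j] <- -U[, j]
  }
  grassmann_point(U, check = FALSE)
}

#' Turn EEG segments into a labeled Grassmann set
#'
#' The full feature pipeline, applied per segment: split into
#' sub-epochs ([split_subepochs()]), compute a log-power spectrogram
#' per sub-epoch ([log_spectrogram()]), and embed the resulting
#' spectrum set as one Grassmann point ([embed_spectrum_set()]). With
#' the defaults each Bonn-length segment (4097 samples) yields M = 8
#' spectrograms of 7 frames x 65 bins, hence one point on
#' G(p, 455).
#'
#' @param segments List of [eeg_segment()]s (e.g. from
#'   [read_bonn_directory()] or [gen_synthetic_eeg()]), all at one
#'   sampling rate.
#' @inheritParams split_subepochs
#' @inheritParams log_spectrogram
#' @inheritParams embed_spectrum_set
#' @return A [grassmann_set()] labeled by the segments' group labels,
#'   with the pipeline configuration attached as attribute `config`.
#' @export
featurize_dataset <- function(segments, subepoch_len = 512L, hop = 512L,
                              stft_window = 128L, stft_overlap = 64L,
                              fft_size = 128L, p = 5L, resize = NULL,
                              eps = 1e-12) {
  stopifnot(is.list(segments), length(segments) >= 1L)
  rates <- vapply(segments, function(s) s$sampling_rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("all segments must share one sampling rate", call. = FALSE)
  }
  pts <- lapply(segments, function(seg) {
    tryCatch({
      wins <- split_subepochs(seg, subepoch_len, hop)
      specs <- lapply(wins, log_spectrogram, sampling_rate = seg$sampling_rate,
                      stft_window = stft_window, stft_overlap = stft_overlap,
                      fft_size = fft_size, eps = eps)
      embed_spectrum_set(specs, p = p, resize = resize)
    }, error = function(e) {
      stop("featurization failed for segment '", seg$source_id, "': ",
           conditionMessage(e), call. = FALSE)
    })
  })
  labels <- vapply(segments, function(s) s$label, character(1))
  out <- grassmann_set(pts, labels)
  attr(out, "config") <- list(
    subepoch_len = subepoch_len, hop = hop, stft_window = stft_window,
    stft_overlap = stft_overlap, fft_size = fft_size, p = p,
    resize = resize, eps = eps, sampling_rate = rates[1L]
  )
  out
}
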