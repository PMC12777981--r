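#' Resample an event to a fixed length by linear interpolation
#'
#' Output position `j` (0-based, `j = 0..F-1`) is the piecewise-linear
#' interpolant of the input evaluated at `j * (T - 1) / (F - 1)`; both endpoints
#' are preserved exactly, and `F = T` returns the trace unchanged. This is the
#' length normalization used for peptide sequencing events (e.g. 500 points).
#'
#' @param event An [event_record] or a bare numeric trace.
#' @param F_len Target length, >= 2.
#' @return A `fixed_trace`: list with `values` (length `F_len`),
#'   `origin = "interpolated"` and an all-false `pad_mask`.
#' @export
resample_linear <- function(event, F_len) {
  trace <- if (inherits(event, "event_record")) event$trace else as.numeric(event)
  T_len <- length(trace)
  if (T_len < 2L) stopf("resample_linear: trace must have length >= 2")
  if (!is_count(F_len) || F_len < 2L) stopf("resample_linear: F_len must be >= 2")
  values <- if (F_len == T_len) trace else
    stats::approx(x = seq_len(T_len), y = trace,
                  xout = 1 + (seq_len(F_len) - 1) * (T_len - 1) / (F_len - 1))$y
  structure(list(values = values, origin = "interpolated",
                 pad_mask = rep(FALSE, F_len)),
            class = "fixed_trace")
}

#' Pad an event to a fixed length, centered
#'
#' Places the trace centrally in a length-`F_len` vector (left pad
#' `floor((F - T) / 2)`), filling pad positions with `pad_value`. This is the
#' convention for event sets whose raw events are all shorter than the target
#' (e.g. 700-element vectors with padding around the events).
#'
#' @param event An [event_record] or numeric trace, length `T <= F_len`.
#' @param F_len Target length.
#' @param pad_value Fill value for pad positions (default 0).
#' @return A `fixed_trace` with `origin = "padded"` and `pad_mask` true at pad
#'   positions.
#' @export
pad_center <- function(event, F_len, pad_value = 0) {
  trace <- if (inherits(event, "event_record")) event$trace else as.numeric(event)
  T_len <- length(trace)
  if (!is_count(F_len)) stopf("pad_center: F_len must be a positive integer")
  if (T_len > F_len)
    stopf("pad_center: trace length %d exceeds target %d (truncate or resample first)",
          T_len, F_len)
  left <- (F_len - T_len) %/% 2L
  right <- F_len - T_len - left
  values <- c(rep(pad_value, left), trace, rep(pad_value, right))
  pad_mask <- c(rep(TRUE, left), rep(FALSE, T_len), rep(TRUE, right))
  structure(list(values = values, origin = "padded", pad_mask = pad_mask),
            class = "fixed_trace")
}

#' Standardize the amplitude of a fixed-length trace
#'
#' `zscore` subtracts the mean and divides by the population standard deviation
#' of the non-pad values (a sigma below `1e-12` is replaced by 1, so constant
#' traces map to zeros); pad positions keep their pad value. `none` is the
#' identity, for inputs already normalized upstream.
#'
#' @param trace A `fixed_trace`.
#' @param mode `"none"` or `"zscore"`.
#' @return A `fixed_trace` of the same shape.
#' @export
standardize_trace <- function(trace, mode = c("none", "zscore")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "fixed_trace"))
  if (mode == "none") return(trace)
  live <- !trace$pad_mask
  x <- trace$values[live]
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma < 1e-12) sigma <- 1
  trace$values[live] <- (x - mu) / sigma
  trace
}

#' Segment a fixed-length trace into non-overlapping subsequences
#'
#' Splits the trace into `L = ceiling(F / w)` windows of length `w` — the token
#' unit of the model, sized so one window approximates the signal span of a
#' single residue. When `w` does not divide `F`, the final window is padded at
#' its tail by replicating its last real value (avoiding a spurious step edge),
#' and the pad count is recorded so concatenating the rows and dropping the last
#' `tail_pad` values reproduces the trace exactly.
#'
#' @param trace A `fixed_trace` or numeric vector.
#' @param w Window length, >= 1.
#' @return A `segmented_event`: list with `subsequences` (`L x w` matrix), `w`,
#'   `L` and `tail_pad`.
#' @export
segment_trace <- function(trace, w) {
  values <- if (inherits(trace, "fixed_trace")) trace$values else as.numeric(trace)
  if (!is_count(w)) stopf("segment_trace: w must be a positive integer")
  F_len <- length(values)
  L <- ceiling(F_len / w)
  tail_pad <- L * w - F_len
  padded <- c(values, rep(values[F_len], tail_pad))
  structure(list(subsequences = matrix(padded, nrow = L, ncol = w, byrow = TRUE),
                 w = as.integer(w), L = as.integer(L),
                 tail_pad = as.integer(tail_pad)),
            class = "segmented_event")
}

#' Reassemble a segmented event into its original trace
#'
#' Inverse of [segment_trace()]: concatenates the rows and drops the
#' `tail_pad` replicated values.
#'
#' @param seg A `segmented_event`.
#' @return Numeric vector of length `L * w - tail_pad`.
#' @export
unsegment_trace <- function(seg) {
  stopifnot(inherits(seg, "segmented_event"))
  x <- as.vector(t(seg$subsequences))
  if (seg$tail_pad > 0L) x <- x[seq_len(length(x) - seg$tail_pad)]
  x
}

#' Draw a random mask plan over L subsequence positions
#'
#' Selects a uniformly random subset of positions (without replacement) to hide
#' during pretraining. The masked count is `round(r * L)` clamped to
#' `[1, L - 1]`, so at least one position is masked and one stays visible —
#' without both, the reconstruction pretext task is undefined. Deterministic
#' given `seed`. Indices are 1-based.
#'
#' @param L Number of subsequences, >= 2.
#' @param r Mask ratio in (0, 1); default 0.6.
#' @param seed Integer seed.
#' @return A `mask_plan`: sorted integer vectors `masked_idx` and
#'   `visible_idx` partitioning `1:L`, plus `r` and `seed`.
#' @export
make_mask <- function(L, r = 0.6, seed = 1L) {
  if (!is_count(L) || L < 2L) stopf("make_mask: L must be an integer >= 2")
  if (!is.numeric(r) || r <= 0 || r >= 1) stopf("make_mask: r must be in (0, 1)")
  n_mask <- min(max(round(r * L), 1L), L - 1L)
  masked <- with_seed(seed, sort(sample.int(L, n_mask)))
  structure(list(masked_idx = masked,
                 visible_idx = setdiff(seq_len(L), masked),
                 r = r, seed = as.integer(seed), L = as.integer(L)),
            class = "mask_plan")
}

#' Preprocess an event set to a fixed length
#'
#' Applies length normalization ([resample_linear()] or [pad_center()]) and
#' optional amplitude standardization to every event, returning a fixed-length
#' [event_set] ready for segmentation and training.
#'
#' @param set An [event_set].
#' @param F_len Target fixed length (e.g. 500 for interpolated peptide reads,
#'   700 for padded carrier events).
#' @param mode `"interpolate"` or `"pad"`.
#' @param standardize `"none"` or `"zscore"` (applied to non-pad values).
#' @param pad_value Fill value when `mode = "pad"`.
#' @return An [event_set] with `fixed_length = F_len`.
#' @export
preprocess_events <- function(set, F_len, mode = c("interpolate", "pad"),
                              standardize = c("none", "zscore"), pad_value = 0) {
  mode <- match.arg(mode)
  standardize <- match.arg(standardize)
  stopifnot(inherits(set, "event_set"))
  events <- lapply(set$events, function(e) {
    ft <- if (mode == "interpolate") resample_linear(e, F_len)
          else pad_center(e, F_len, pad_value)
    ft <- standardize_trace(ft, standardize)
    event_record(e$id, ft$values, e$label, e$source, e$duration_points)
  })
  event_set(events, fixed_length = as.integer(F_len))
}

# Segment every event of a fixed-length set into one row-stacked matrix:
# (B * L) x w, event-major (rows (b-1)*L + 1 .. b*L belong to event b).
segment_batch <- function(set, w) {
  stopifnot(inherits(set, "event_set"))
  if (is.null(set$fixed_length))
    stopf("segment_batch: event_set must be preprocessed to a fixed length")
  B <- length(set$events)
  if (!B) stopf("segment_batch: empty event_set")
  s1 <- segment_trace(set$events[[1L]]$trace, w)
  L <- s1$L
  seg <- matrix(0, nrow = B * L, ncol = w)
  seg[seq_len(L), ] <- s1$subsequences
  if (B > 1L) for (b in 2:B) {
    seg[((b - 1L) * L + 1L):(b * L), ] <-
      segment_trace(set$events[[b]]$trace, w)$subsequences
  }
  list(seg = seg, B = B, L = L, w = as.integer(w),
       ids = event_ids(set), labels = event_labels(set),
       tail_pad = s1$tail_pad)
}
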