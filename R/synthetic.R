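#' Amino-acid residue volumes
#'
#' Reads the vendored residue-volume table (Zamyatnin 1972, nm^3) shipped with
#' the package. Only volume *differences* between residues drive class
#' separation in the simulator, so any standard table serves; entries can be
#' overridden or extended (e.g. with modified-residue codes) via `overrides`.
#'
#' @param overrides Optional named numeric vector of volumes (nm^3) that
#'   replace or extend table entries, e.g. `c(X = 0.1455)` for a
#'   phosphorylated serine.
#' @return Named numeric vector, one-letter residue code to volume in nm^3.
#' @export
aa_volumes <- function(overrides = NULL) {
  path <- system.file("extdata", "aa_volumes.tsv", package = "poremae")
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE)
  vol <- stats::setNames(tab$volume_nm3, tab$residue)
  if (!is.null(overrides)) vol[names(overrides)] <- overrides
  vol
}

#' Reference 42-residue peptide sequence
#'
#' The human amyloid-beta 1-42 primary structure (UniProt P05067, residues
#' 672-713), used as the default sequence for the peptide simulator. Position
#' 22 is glutamic acid (the E22G mutation site), position 37 glycine (G37R)
#' and position 26 serine (the phosphorylation site).
#'
#' @return A single 42-character string of one-letter residue codes.
#' @export
abeta42_sequence <- function() "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

#' Apply a point substitution to a residue sequence
#'
#' @param sequence One-letter residue string.
#' @param position_1based Position to substitute (1-based).
#' @param new_residue Single one-letter code.
#' @return The mutated sequence; all other positions unchanged.
#' @export
mutate_sequence <- function(sequence, position_1based, new_residue) {
  n <- nchar(sequence)
  if (!is_count(position_1based) || position_1based > n)
    stopf("mutate_sequence: position %s out of range 1..%d",
          format(position_1based), n)
  if (nchar(new_residue) != 1L)
    stopf("mutate_sequence: 'new_residue' must be a single residue code")
  paste0(substr(sequence, 1L, position_1based - 1L), new_residue,
         substr(sequence, position_1based + 1L, n))
}

#' Simulation parameters for barcode-carrier events
#'
#' Emulates DNA-carrier translocation events in which hairpin-loop structures
#' at known positions produce characteristic current spikes encoding a binary
#' barcode, optionally with a protein bound at a site in the latter half of the
#' carrier. Blockades are negative (deeper blockade = more negative); spikes
#' deflect further downward from the carrier level.
#'
#' @param n_bits Barcode length (default 3, giving 8 classes).
#' @param carrier_level Baseline blockade depth of the bare carrier
#'   (magnitude, arbitrary units).
#' @param spike_amp Additional downward deflection of a barcode spike.
#' @param spike_width_points Width of each spike in sampling points.
#' @param event_len_range Integer pair: raw event length is drawn uniformly
#'   from this range.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise.
#' @param binding_site `"none"` (barcode task), `"unbound"` or `"bound"`.
#' @param binding_amp Downward deflection of the bound-protein spike.
#' @param seed Integer seed.
#' @return An object of class `barcode_sim_params`.
#' @export
barcode_sim_params <- function(n_bits = 3L, carrier_level = 0.3,
                               spike_amp = 0.35, spike_width_points = 30L,
                               event_len_range = c(450L, 650L),
                               noise_sd = 0.04,
                               binding_site = c("none", "unbound", "bound"),
                               binding_amp = 0.3, seed = 1L) {
  binding_site <- match.arg(binding_site)
  stopifnot(is_count(n_bits), is_count(spike_width_points),
            length(event_len_range) == 2L, noise_sd >= 0)
  min_len <- 2L * n_bits * spike_width_points + 2L * spike_width_points
  if (event_len_range[1L] < min_len)
    stopf("barcode_sim_params: events of length %d cannot fit %d spike sites of width %d",
          event_len_range[1L], n_bits, spike_width_points)
  structure(list(n_bits = as.integer(n_bits), carrier_level = carrier_level,
                 spike_amp = spike_amp,
                 spike_width_points = as.integer(spike_width_points),
                 event_len_range = as.integer(event_len_range),
                 noise_sd = noise_sd, binding_site = binding_site,
                 binding_amp = binding_amp, seed = as.integer(seed)),
            class = "barcode_sim_params")
}

# Noiseless barcode template of a given length (deterministic geometry).
barcode_template <- function(barcode, params, len) {
  bits <- as.integer(strsplit(barcode, "")[[1L]])
  x <- rep(-params$carrier_level, len)
  half <- len %/% 2L
  wd <- params$spike_width_points
  for (i in seq_len(params$n_bits)) {
    if (bits[i] == 1L) {
      center <- round((i - 0.5) / params$n_bits * half)
      lo <- max(1L, center - wd %/% 2L)
      hi <- min(len, lo + wd - 1L)
      x[lo:hi] <- x[lo:hi] - params$spike_amp
    }
  }
  if (params$binding_site == "bound") {
    center <- round(0.75 * len)
    lo <- max(1L, center - wd %/% 2L)
    hi <- min(len, lo + wd - 1L)
    x[lo:hi] <- x[lo:hi] - params$binding_amp
  }
  x
}

#' Simulate one barcode-carrier translocation event
#'
#' The event is a baseline blockade at `-carrier_level` over a random length,
#' with a downward spike at the i-th equally spaced site of the first half iff
#' bit i of the barcode is 1, an additional spike at the binding site in the
#' latter half iff `binding_site = "bound"`, plus Gaussian noise. Deterministic
#' given `params$seed`.
#'
#' @param barcode Bit-string of length `n_bits`, e.g. `"101"`.
#' @param params A [barcode_sim_params].
#' @param id Event id.
#' @param label Event label; defaults to the barcode (or to the binding state
#'   for the binding task).
#' @return An [event_record].
#' @export
simulate_barcode_event <- function(barcode, params, id = "bc1", label = NULL) {
  stopifnot(inherits(params, "barcode_sim_params"))
  if (nchar(barcode) != params$n_bits ||
      grepl("[^01]", barcode))
    stopf("simulate_barcode_event: barcode must be %d bits of 0/1", params$n_bits)
  if (is.null(label))
    label <- if (params$binding_site == "none") barcode else params$binding_site
  trace <- with_seed(params$seed, {
    # sample() treats a length-1 vector as 1:n, so guard degenerate ranges
    len <- if (params$event_len_range[1L] == params$event_len_range[2L])
      params$event_len_range[1L]
    else sample(params$event_len_range[1L]:params$event_len_range[2L], 1L)
    tmpl <- barcode_template(barcode, params, len)
    tmpl + stats::rnorm(len, sd = params$noise_sd)
  })
  event_record(id = id, trace = trace, label = label, source = "sim_barcode")
}

#' Simulation parameters for peptide translocation events
#'
#' Emulates single-file peptide reads through an ultrathin solid-state pore:
#' residue `i` occupies a gamma-distributed dwell (mean `dwell_mean_points`,
#' shape `dwell_shape`) at blockade depth
#' `-depth_per_volume * volume(residue i)` — larger residue volume, deeper
#' (more negative) blockade. Gaussian noise is added and the trace is linearly
#' resampled to `out_len` points, mirroring the length normalization applied to
#' real reads.
#'
#' Defaults are chosen so that a single-residue volume change of ~0.09 nm^3
#' shifts the local blockade by about twice the per-point noise sd over a
#' ~12-point dwell window — a discriminability comparable to published
#' single-residue nanopore assays.
#'
#' @param sequence One-letter residue string (default the 42-residue reference
#'   of [abeta42_sequence()]).
#' @param volume_table Named volumes in nm^3 (default [aa_volumes()]); every
#'   residue of `sequence` must have an entry.
#' @param depth_per_volume Blockade units per nm^3 (default 2.0).
#' @param dwell_mean_points,dwell_shape Gamma dwell-time parameters: mean dwell
#'   per residue in points, and the shape (default 400, i.e. dwell CV 0.05,
#'   reflecting near-constant translocation velocity through an ultrathin
#'   pore; lower shapes give heavier-tailed dwells).
#' @param noise_sd Gaussian noise sd (default 0.08, "moderate").
#' @param out_len Output length after linear resampling (default 500).
#' @param seed Integer seed.
#' @return An object of class `peptide_sim_params`.
#' @export
peptide_sim_params <- function(sequence = abeta42_sequence(),
                               volume_table = aa_volumes(),
                               depth_per_volume = 2.0,
                               dwell_mean_points = 12, dwell_shape = 400,
                               noise_sd = 0.08, out_len = 500L, seed = 1L) {
  res <- strsplit(sequence, "")[[1L]]
  missing <- setdiff(res, names(volume_table))
  if (length(missing))
    stopf("peptide_sim_params: no volume entry for residue(s): %s",
          paste(unique(missing), collapse = ", "))
  if (!is_count(out_len) || out_len < 2L)
    stopf("peptide_sim_params: out_len must be >= 2")
  stopifnot(noise_sd >= 0, dwell_mean_points > 0, dwell_shape > 0)
  structure(list(sequence = sequence, volume_table = volume_table,
                 depth_per_volume = depth_per_volume,
                 dwell_mean_points = dwell_mean_points,
                 dwell_shape = dwell_shape, noise_sd = noise_sd,
                 out_len = as.integer(out_len), seed = as.integer(seed)),
            class = "peptide_sim_params")
}

#' Simulate one peptide translocation event
#'
#' Builds the piecewise-constant latent signal (one dwell segment per residue
#' at its volume-scaled depth), adds Gaussian noise, and resamples to
#' `out_len` points via [resample_linear()]. Deterministic given `params$seed`.
#'
#' @param params A [peptide_sim_params].
#' @param id Event id.
#' @param label Class label supplied by the caller (e.g. the variant name).
#' @return An [event_record]; `duration_points` records the raw length before
#'   resampling.
#' @export
simulate_peptide_event <- function(params, id = "pep1", label = "") {
  stopifnot(inherits(params, "peptide_sim_params"))
  res <- strsplit(params$sequence, "")[[1L]]
  depths <- -params$depth_per_volume * unname(params$volume_table[res])
  trace_raw <- with_seed(params$seed, {
    dwell <- pmax(1L, round(stats::rgamma(length(res), shape = params$dwell_shape,
                                          scale = params$dwell_mean_points /
                                            params$dwell_shape)))
    latent <- rep(depths, times = dwell)
    latent + stats::rnorm(length(latent), sd = params$noise_sd)
  })
  ft <- resample_linear(trace_raw, params$out_len)
  event_record(id = id, trace = ft$values, label = label, source = "sim_peptide",
               duration_points = length(trace_raw))
}

# Noiseless, constant-dwell template of a peptide class (used by the
# nearest-template oracle and template-separability checks).
peptide_template <- function(params) {
  res <- strsplit(params$sequence, "")[[1L]]
  depths <- -params$depth_per_volume * unname(params$volume_table[res])
  latent <- rep(depths, each = max(1L, round(params$dwell_mean_points)))
  resample_linear(latent, params$out_len)$values
}

#' Generate a labeled synthetic event dataset
#'
#' Seeded fixture generator for the three task families: `"barcode8"` (all
#' `2^n_bits` barcode classes), `"binding2"` (bound vs unbound carriers with
#' random barcodes), and `"peptide"` (one class per sequence variant).
#' Per-event seeds are derived deterministically from `seed`, so the same call
#' yields a byte-identical dataset. A manifest of every parameter is attached
#' as attribute `"manifest"`.
#'
#' @param task `"barcode8"`, `"binding2"` or `"peptide"`.
#' @param n_per_class Events per class: a single integer, or a named vector
#'   (per class) for deliberately imbalanced designs.
#' @param params A [barcode_sim_params] or [peptide_sim_params] for the task.
#' @param class_defs For `"peptide"`: named character vector of sequences, one
#'   per class (default: the reference sequence plus its E22G and G37R
#'   mutants). Ignored for the carrier tasks.
#' @param seed Integer master seed.
#' @return A labeled [event_set] with a `"manifest"` attribute.
#' @export
generate_dataset <- function(task = c("barcode8", "binding2", "peptide"),
                             n_per_class, params = NULL, class_defs = NULL,
                             seed = 1L) {
  task <- match.arg(task)
  if (task %in% c("barcode8", "binding2")) {
    if (is.null(params)) params <- barcode_sim_params()
    stopifnot(inherits(params, "barcode_sim_params"))
    classes <- if (task == "barcode8") {
      apply(expand.grid(rep(list(0:1), params$n_bits))[, params$n_bits:1,
                                                       drop = FALSE],
            1L, paste, collapse = "")
    } else c("unbound", "bound")
  } else {
    if (is.null(params)) params <- peptide_sim_params()
    stopifnot(inherits(params, "peptide_sim_params"))
    if (is.null(class_defs)) {
      ref <- abeta42_sequence()
      class_defs <- c(native = ref,
                      E22G = mutate_sequence(ref, 22L, "G"),
                      G37R = mutate_sequence(ref, 37L, "R"))
    }
    if (is.null(names(class_defs)) || any(!nzchar(names(class_defs))))
      stopf("generate_dataset: peptide class_defs must be a named character vector")
    classes <- names(class_defs)
  }
  counts <- if (length(n_per_class) == 1L)
    stats::setNames(rep(as.integer(n_per_class), length(classes)), classes)
  else {
    if (is.null(names(n_per_class)) || !setequal(names(n_per_class), classes))
      stopf("generate_dataset: named n_per_class must cover exactly the classes")
    as.integer(n_per_class[classes])
  }
  if (any(counts < 1L)) stopf("generate_dataset: n_per_class must be >= 1")
  events <- list()
  k <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    for (i in seq_len(counts[[ci]])) {
      k <- k + 1L
      ev_seed <- mix_seed(seed, ci, i)
      id <- sprintf("%s_%s_%04d", task, cl, i)
      events[[k]] <- switch(
        task,
        barcode8 = {
          p <- params; p$seed <- ev_seed
          simulate_barcode_event(cl, p, id = id, label = cl)
        },
        binding2 = {
          p <- params; p$seed <- ev_seed
          p$binding_site <- cl
          bc <- with_seed(mix_seed(ev_seed, 3L),
                          paste(sample(0:1, p$n_bits, replace = TRUE),
                                collapse = ""))
          simulate_barcode_event(bc, p, id = id, label = cl)
        },
        peptide = {
          p <- params; p$seed <- ev_seed
          p$sequence <- class_defs[[cl]]
          simulate_peptide_event(p, id = id, label = cl)
        })
    }
  }
  out <- event_set(events)
  attr(out, "manifest") <- list(task = task, classes = as.list(counts),
                                seed = as.integer(seed),
                                params = unclass(params)[setdiff(names(unclass(params)),
                                                                 "volume_table")],
                                sign_convention = "deeper blockade = more negative")
  out
}

#' Named fixture recipes
#'
#' Loads one of the checked-in dataset recipes (`inst/extdata/recipes/`) and
#' generates it: `"barcode8-easy"`, `"binding2-easy"`, `"abeta3-default"` (three
#' peptide classes — reference, E22G, G37R — at 200 events each under moderate
#' noise) and `"abeta3-noiseless"`.
#'
#' @param name Recipe name.
#' @param seed Master seed (default: the recipe's own).
#' @return A labeled [event_set].
#' @export
fixture_recipe <- function(name, seed = NULL) {
  path <- system.file("extdata", "recipes", paste0(name, ".yaml"),
                      package = "poremae")
  if (!nzchar(path)) stopf("fixture_recipe: unknown recipe '%s'", name)
  rc <- yaml::read_yaml(path)
  if (is.null(seed)) seed <- rc$seed
  params <- if (rc$task == "peptide") {
    do.call(peptide_sim_params, rc$params)
  } else do.call(barcode_sim_params, rc$params)
  generate_dataset(task = rc$task, n_per_class = rc$n_per_class,
                   params = params, seed = seed)
}

#' Nearest-template classification
#'
#' Independent oracle classifier for simulated datasets: each class is
#' represented by its noiseless constant-dwell template (peptide tasks) or its
#' noiseless geometry at the mean event length (carrier tasks), resampled to
#' the event length, and each event is assigned the class of the nearest
#' template in L2 distance. At zero noise this classifier is exact, which
#' bounds the difficulty of every simulated task from below.
#'
#' @param events An [event_set] from [generate_dataset()].
#' @param task The generating task.
#' @param params The generating parameter object.
#' @param class_defs As in [generate_dataset()] (peptide task).
#' @return Character vector of predicted labels.
#' @export
nearest_template <- function(events, task = c("barcode8", "binding2", "peptide"),
                             params = NULL, class_defs = NULL) {
  task <- match.arg(task)
  if (task == "peptide") {
    if (is.null(params)) params <- peptide_sim_params()
    if (is.null(class_defs)) {
      ref <- abeta42_sequence()
      class_defs <- c(native = ref, E22G = mutate_sequence(ref, 22L, "G"),
                      G37R = mutate_sequence(ref, 37L, "R"))
    }
    templates <- lapply(class_defs, function(s) {
      p <- params; p$sequence <- s
      peptide_template(p)
    })
    vapply(events$events, function(e) {
      tr <- if (length(e$trace) == params$out_len) e$trace
            else resample_linear(e$trace, params$out_len)$values
      names(class_defs)[which.min(vapply(templates, function(t)
        sum((tr - t)^2), 0))]
    }, "")
  } else {
    if (is.null(params)) params <- barcode_sim_params()
    classes <- if (task == "barcode8")
      apply(expand.grid(rep(list(0:1), params$n_bits))[, params$n_bits:1,
                                                       drop = FALSE],
            1L, paste, collapse = "")
    else c("unbound", "bound")
    vapply(events$events, function(e) {
      len <- length(e$trace)
      tmpl <- lapply(classes, function(cl) {
        p <- params
        if (task == "binding2") { p$binding_site <- cl; cl <- paste(rep("0", p$n_bits), collapse = "") }
        barcode_template(cl, p, len)
      })
      # binding task: compare only the binding-site window (barcodes vary)
      if (task == "binding2") {
        win <- max(1L, round(0.75 * len) - params$spike_width_points):
          min(len, round(0.75 * len) + params$spike_width_points)
        classes[which.min(vapply(tmpl, function(t)
          sum((e$trace[win] - t[win])^2), 0))]
      } else {
        classes[which.min(vapply(tmpl, function(t) sum((e$trace - t)^2), 0))]
      }
    }, "")
  }
}
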