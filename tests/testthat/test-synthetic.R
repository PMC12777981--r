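test_that("barcode events encode bits as localized spikes", {
  p0 <- barcode_sim_params(noise_sd = 0, event_len_range = c(500L, 500L))
  flat <- simulate_barcode_event("000", p0)
  expect_true(all(flat$trace == -p0$carrier_level))
  a <- simulate_barcode_event("101", p0)$trace
  b <- simulate_barcode_event("001", p0)$trace
  diffpos <- which(a != b)
  # differ only within site 0's spike window (first half, first site)
  expect_true(all(diffpos <= 250 / 3 + p0$spike_width_points))
  expect_equal(max(abs(a - b)), p0$spike_amp)
  # all 8 noiseless templates are pairwise distinct by at least spike_amp/2
  tmpl <- lapply(sprintf("%03d", c(0, 1, 10, 11, 100, 101, 110, 111)),
                 function(bc) simulate_barcode_event(
                   gsub(" ", "0", sprintf("%3s", bc)), p0)$trace)
  combs <- utils::combn(8, 2)
  for (k in seq_len(ncol(combs))) {
    d <- max(abs(tmpl[[combs[1, k]]] - tmpl[[combs[2, k]]]))
    expect_gte(d, p0$spike_amp / 2)
  }
  # bound carriers differ from unbound only in the latter half
  pb <- p0; pb$binding_site <- "bound"
  bound <- simulate_barcode_event("010", pb, label = "bound")$trace
  unb <- simulate_barcode_event("010", p0)$trace
  expect_true(all(which(bound != unb) > 250))
  expect_error(simulate_barcode_event("10", p0), "3 bits")
})

test_that("peptide events scale local depth with residue volume", {
  # equal-volume residues at zero noise give a flat trace
  p <- peptide_sim_params(sequence = "GGGG", noise_sd = 0, out_len = 50L)
  flat <- simulate_peptide_event(p)
  expect_equal(diff(range(flat$trace)), 0)
  # the spec'd mutation deltas: install a table carrying the printed volume
  # differences, then the noiseless constant-dwell templates differ only in
  # the mutated residue's dwell window, by depth_per_volume * delta
  vt <- aa_volumes()
  vt[["G"]] <- vt[["E"]] - 0.0887  # E22G local volume change
  ref <- abeta42_sequence()
  p_wt <- peptide_sim_params(sequence = ref, volume_table = vt, noise_sd = 0)
  p_mu <- peptide_sim_params(sequence = mutate_sequence(ref, 22, "G"),
                             volume_table = vt, noise_sd = 0)
  t_wt <- poremae:::peptide_template(p_wt)
  t_mu <- poremae:::peptide_template(p_mu)
  diffpos <- which(abs(t_wt - t_mu) > 1e-12)
  # residue 22 occupies raw points 253..264 of 504 -> resampled window nearby
  expect_true(all(diffpos >= 245 & diffpos <= 270))
  expect_equal(max(abs(t_wt - t_mu)), 2.0 * 0.0887, tolerance = 1e-10)

  # determinism: same seed identical, different seeds differ
  e1 <- simulate_peptide_event(peptide_sim_params(seed = 5))
  e2 <- simulate_peptide_event(peptide_sim_params(seed = 5))
  e3 <- simulate_peptide_event(peptide_sim_params(seed = 6))
  expect_identical(e1$trace, e2$trace)
  expect_false(identical(e1$trace, e3$trace))
  expect_error(peptide_sim_params(sequence = "AZJ"), "no volume entry")
})

test_that("mutations substitute exactly one position and invert cleanly", {
  ref <- abeta42_sequence()
  expect_identical(nchar(ref), 42L)
  m37 <- mutate_sequence(ref, 37, "R")
  expect_identical(substr(m37, 37, 37), "R")
  expect_identical(which(strsplit(ref, "")[[1]] != strsplit(m37, "")[[1]]), 37L)
  m22 <- mutate_sequence(ref, 22, "G")
  expect_identical(substr(m22, 22, 22), "G")
  expect_identical(mutate_sequence(m22, 22, "E"), ref)  # involution
  expect_error(mutate_sequence(ref, 43, "A"), "out of range")
})

test_that("generated datasets have the requested composition and are byte-stable", {
  ds <- generate_dataset("barcode8", n_per_class = 10L, seed = 3)
  expect_length(ds, 80L)
  expect_length(ds$class_names, 8L)
  pep <- generate_dataset("peptide", n_per_class = 2L, seed = 3)
  expect_identical(pep$class_names, c("native", "E22G", "G37R"))
  expect_false(is.null(attr(pep, "manifest")))
  # deliberate imbalance
  imb <- generate_dataset("binding2",
                          n_per_class = c(bound = 3L, unbound = 7L), seed = 3)
  expect_identical(as.integer(table(vapply(imb$events, `[[`, "", "label"))),
                   c(3L, 7L))
  # byte-identical NDJSON from the same spec
  f1 <- tempfile(); f2 <- tempfile()
  write_events(generate_dataset("peptide", 2L, seed = 9), f1, "ndjson")
  write_events(generate_dataset("peptide", 2L, seed = 9), f2, "ndjson")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("nearest-template oracle is exact at zero noise in the template regime", {
  # no amplitude noise; default near-constant translocation velocity
  p <- peptide_sim_params(noise_sd = 0)
  ds <- generate_dataset("peptide", 20L, params = p, seed = 31)
  preds <- nearest_template(ds, "peptide", params = p)
  expect_equal(mean(preds == vapply(ds$events, `[[`, "", "label")), 1.0)
  # barcode task, zero noise
  pb <- barcode_sim_params(noise_sd = 0)
  db <- generate_dataset("barcode8", 5L, params = pb, seed = 33)
  pr <- nearest_template(db, "barcode8", params = pb)
  expect_equal(mean(pr == vapply(db$events, `[[`, "", "label")), 1.0)
})

test_that("oracle accuracy degrades monotonically with the noise knob", {
  grid <- c(0.05, 0.2, 0.45, 0.8)
  acc <- matrix(0, 3, length(grid))
  for (s in 1:3) {
    for (g in seq_along(grid)) {
      p <- peptide_sim_params(noise_sd = grid[g])
      ds <- generate_dataset("peptide", 25L, params = p, seed = 100 * s + g)
      preds <- nearest_template(ds, "peptide", params = p)
      acc[s, g] <- mean(preds == vapply(ds$events, `[[`, "", "label"))
    }
  }
  mean_acc <- colMeans(acc)
  expect_true(all(diff(mean_acc) <= 0.02))  # monotone within sampling error
  expect_gt(mean_acc[1], mean_acc[length(grid)])
})

test_that("dwell durations average to the configured mean", {
  p <- peptide_sim_params()
  durs <- vapply(1:1000, function(i) {
    pp <- p; pp$seed <- i
    simulate_peptide_event(pp)$duration_points
  }, 0L)
  mean_dwell <- mean(durs) / nchar(p$sequence)
  expect_lt(abs(mean_dwell - p$dwell_mean_points), 0.1 * p$dwell_mean_points)
})

test_that("template separation is ordered by the published volume deltas", {
  # phosphorylation (+0.0565) < E22G (0.0887) < G37R (0.1357)
  vt <- aa_volumes(overrides = c(X = aa_volumes()[["S"]] + 0.0565))
  vt[["G"]] <- vt[["E"]] - 0.0887
  vt[["R"]] <- vt[["G"]] + 0.1357
  ref <- abeta42_sequence()
  tmpl <- function(seq) poremae:::peptide_template(
    peptide_sim_params(sequence = seq, volume_table = vt, noise_sd = 0))
  t_ref <- tmpl(ref)
  d_ptm <- max(abs(tmpl(mutate_sequence(ref, 26, "X")) - t_ref))
  d_e22g <- max(abs(tmpl(mutate_sequence(ref, 22, "G")) - t_ref))
  d_g37r <- max(abs(tmpl(mutate_sequence(ref, 37, "R")) - t_ref))
  expect_lt(d_ptm, d_e22g)
  expect_lt(d_e22g, d_g37r)
})

test_that("fixture recipes load and regenerate deterministically", {
  ds <- fixture_recipe("barcode8-easy")
  expect_length(ds, 8L * 30L)
  ds2 <- fixture_recipe("barcode8-easy")
  expect_identical(lapply(ds$events, `[[`, "trace"),
                   lapply(ds2$events, `[[`, "trace"))
  expect_error(fixture_recipe("nope"), "unknown recipe")
})
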