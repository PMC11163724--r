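# Synthetic-data generators: determinism, degenerate limits, truth-table
# consistency, and round-trips through the package readers.

test_that("generators are seed-deterministic", {
  cfg <- sim_config(seed = 21, junctions = list(
    n_constitutive = 10, n_skiptic = 3, read_depth = 200))
  a <- simulate_junctions(cfg)
  b <- simulate_junctions(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_genome(cfg)$genome, simulate_genome(cfg)$genome)
  expect_identical(simulate_dose(cfg)$observations,
                   simulate_dose(cfg)$observations)
  # a different seed changes the draws
  c2 <- simulate_junctions(sim_config(seed = 22, junctions = list(
    n_constitutive = 10, n_skiptic = 3, read_depth = 200)))
  expect_false(identical(a$samples, c2$samples))
})

test_that("degenerate PSI values produce degenerate read counts", {
  cfg <- sim_config(seed = 23, junctions = list(
    n_constitutive = 5, n_skiptic = 5, read_depth = 400,
    min_psi_constitutive = 0.9999, skiptic_delta = c(-1, -1)))
  sim <- simulate_junctions(cfg)
  truth <- sim$truth
  # control PSI ~ 1: essentially no exclusion junctions in control samples
  ctrl <- sim$samples[["ctrl_1"]]
  excl <- ctrl[ctrl$end - ctrl$start > 1000, ]
  expect_lte(sum(excl$reads), 2)  # Pois(400 * (1 - 0.9999)) per exon
  # treated PSI = 0 for skiptic exons: no inclusion reads at their sites
  sk <- truth[truth$is_skiptic & truth$psi_treated == 0, ]
  trt <- sim$samples[["tdp_1"]]
  for (i in seq_len(nrow(sk))) {
    at_sites <- trt[trt$end == sk$start[i] | trt$start == sk$end[i], ]
    expect_equal(sum(at_sites$reads), 0)
  }
})

test_that("emitted junction files validate against the package readers", {
  d <- tempfile()
  cfg <- sim_config(seed = 24, junctions = list(
    n_constitutive = 8, n_skiptic = 2, read_depth = 150))
  sim <- simulate_junctions(cfg, dir = d)
  for (nm in names(sim$samples)) {
    back <- read_junction_bed(file.path(d, "junctions", paste0(nm, ".bed")),
                              nm)
    expect_equal(back, sim$samples[[nm]])
  }
  ex <- read_exons_gtf(file.path(d, "annotation.gtf"))
  expect_equal(ex$start, sim$exons$start)
  expect_equal(ex$exon_id, sim$exons$exon_id)
})

test_that("pooled PSI estimates track the generating truth", {
  cfg <- sim_config(seed = 25, junctions = list(
    n_constitutive = 40, n_skiptic = 10, read_depth = 800))
  sim <- simulate_junctions(cfg)
  pc <- psi_matrix(sim$exons, sample_indexes(sim, "ctrl"))
  pt <- psi_matrix(sim$exons, sample_indexes(sim, "tdp"))
  d <- delta_psi(pc, pt)
  m <- match(sim$truth$exon_id, d$exon_id)
  expect_lt(max(abs(d$psi_control[m] - sim$truth$psi_control)), 0.05)
  expect_lt(max(abs(d$psi_treated[m] - sim$truth$psi_treated)), 0.05)
})

test_that("planted repeat runs give the expected exact profiles", {
  cfg <- sim_config(seed = 26, genome = list(n_exons = 8))
  gn <- simulate_genome(cfg)
  p3 <- splice_site_profile(gn$exons, gn$genome, "3SS")
  planted <- p3$offset %in% 10:29
  expect_true(all(p3$frequency[planted] == 1))
  expect_true(all(p3$frequency[!planted] == 0))
  expect_true(all(splice_site_profile(gn$exons, gn$genome,
                                      "5SS")$frequency == 0))
})

test_that("planting in half the exons halves the profile height", {
  cfg <- sim_config(seed = 27, genome = list(n_exons = 8,
                                             prop_planted = 0.5))
  gn <- simulate_genome(cfg)
  p3 <- splice_site_profile(gn$exons, gn$genome, "3SS")
  expect_equal(unique(p3$frequency[p3$offset %in% 10:29]), 0.5)
  # no planted repeats at all: all-zero profile
  cfg0 <- sim_config(seed = 27, genome = list(n_exons = 4,
                                              prop_planted = 0))
  gn0 <- simulate_genome(cfg0)
  expect_true(all(splice_site_profile(gn0$exons, gn0$genome,
                                      "3SS")$frequency == 0))
})

test_that("mixed-strand fixtures stay exact with the two-strand-safe background", {
  cfg <- sim_config(seed = 28, genome = list(
    n_exons = 6, strands = "both", background = c("A", "T")))
  gn <- simulate_genome(cfg)
  p3 <- splice_site_profile(gn$exons, gn$genome, "3SS")
  planted <- p3$offset %in% 10:29
  expect_true(all(p3$frequency[planted] == 1))
  expect_true(all(p3$frequency[!planted] == 0))
})

test_that("overlapping planted repeats are rejected", {
  cfg <- sim_config(seed = 29, genome = list(
    n_exons = 2,
    repeat_spec = data.frame(anchor = c("3SS", "3SS"), offset = c(10L, 15L),
                             units = c(10L, 10L))))
  expect_error(simulate_genome(cfg), "overlapping planted repeats")
})

test_that("dose generator enforces monotone knots and records truth", {
  cfg <- sim_config(seed = 30, dose = list(
    knots = data.frame(fold = c(1, 1.5, 2), skipping = c(0, 50, 40))))
  expect_error(simulate_dose(cfg), "non-decreasing")
  ds <- simulate_dose(sim_config(seed = 30))
  expect_equal(ds$truth$diffusion_fraction, 0.45)
  expect_true(all(ds$observations$skipping_percent >= 0 &
                    ds$observations$skipping_percent <= 100))
})

test_that("the full bundle is written once and is re-runnable byte-identically", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- sim_config(seed = 31, junctions = list(
    n_constitutive = 6, n_skiptic = 2, read_depth = 120))
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  files <- c("annotation.gtf", "genome.fa", "dose.tsv",
             "junctions/ctrl_1.bed", "truth/junction_truth.tsv")
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
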