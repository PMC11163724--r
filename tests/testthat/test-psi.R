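# PSI quantification: site assignment, coverage gating, aggregation, and
# agreement with the brute-force interval classifier.

mk_exon <- function(start, end, strand = "+", chrom = "c1", id = "x") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             exon_id = id, stringsAsFactors = FALSE)
}

mk_junctions <- function(start, end, reads, strand = "+", chrom = "c1",
                         sample_id = "s1") {
  junction_table(chrom, start, end, strand, reads, sample_id)
}

test_that("acceptor lookups sum reads and empty indexes return zero", {
  jx <- mk_junctions(c(900, 950), c(1000, 1000), c(30, 20))
  idx <- index_junctions(jx)
  est <- compute_psi(mk_exon(1000, 1100), idx)
  expect_equal(est$inclusion_reads_3ss, 50)

  empty <- index_junctions(mk_junctions(integer(0), integer(0), integer(0)))
  est0 <- compute_psi(mk_exon(1000, 1100), empty)
  expect_equal(est0$inclusion_reads_3ss + est0$inclusion_reads_5ss +
                 est0$exclusion_reads, 0)
  expect_true(is.na(est0$psi))
  expect_false(est0$covered)
})

test_that("duplicated junction intervals merge with summed reads and a warning", {
  jx <- rbind(mk_junctions(100, 200, 5), mk_junctions(100, 200, 7))
  expect_warning(idx <- index_junctions(jx), "merging")
  expect_equal(nrow(idx$junctions), 1L)
  expect_equal(idx$junctions$reads, 12L)
})

test_that("PSI follows the inclusion/exclusion ratio definition", {
  # I3 = 90, I5 = 90, E = 10 -> psi3 = psi5 = psi = 0.9
  jx <- mk_junctions(c(900, 1100, 850), c(1000, 1200, 1250), c(90, 90, 10))
  est <- compute_psi(mk_exon(1000, 1100), index_junctions(jx))
  expect_equal(est$psi3, 0.9)
  expect_equal(est$psi5, 0.9)
  expect_equal(est$psi, 0.9)
  expect_true(est$covered)

  # fully skipped limit: I3 = I5 = 0, E = 25 -> psi = 0, covered at 10
  jx2 <- mk_junctions(850, 1250, 25)
  est2 <- compute_psi(mk_exon(1000, 1100), index_junctions(jx2))
  expect_equal(est2$psi, 0)
  expect_true(est2$covered)

  # defined but under-covered: I3 = 3, I5 = 2, E = 1 at min_reads = 10
  jx3 <- mk_junctions(c(900, 1100, 850), c(1000, 1200, 1250), c(3, 2, 1))
  est3 <- compute_psi(mk_exon(1000, 1100), index_junctions(jx3))
  expect_equal(est3$psi3, 3 / 4)
  expect_equal(est3$psi5, 2 / 3)
  expect_false(est3$covered)
})

test_that("acceptor/donor assignment respects strand", {
  # '-' exon: a junction STARTING at the exon end is 3'SS inclusion
  jx <- mk_junctions(1100, 1200, 40, strand = "-")
  est <- compute_psi(mk_exon(1000, 1100, strand = "-"),
                     index_junctions(jx))
  expect_equal(est$inclusion_reads_3ss, 40)
  expect_equal(est$inclusion_reads_5ss, 0)
})

test_that("boundary-touching junctions are inclusion, never exclusion", {
  # junction ending exactly at exon start must not count as spanning
  jx <- mk_junctions(c(900, 900), c(1000, 1101), c(10, 10))
  est <- compute_psi(mk_exon(1000, 1100), index_junctions(jx))
  expect_equal(est$inclusion_reads_3ss, 10)
  expect_equal(est$exclusion_reads, 10)  # only the strict spanner
})

test_that("unstranded junctions are excluded unless the permissive flag is set", {
  jx <- mk_junctions(900, 1000, 25, strand = ".")
  idx <- index_junctions(jx)
  strict <- compute_psi(mk_exon(1000, 1100), idx)
  expect_equal(strict$inclusion_reads_3ss, 0)
  permissive <- compute_psi(mk_exon(1000, 1100), idx,
                            include_unstranded = TRUE)
  expect_equal(permissive$inclusion_reads_3ss, 25)
})

test_that("compute_psi matches the brute-force classifier on random instances", {
  set.seed(2024)
  for (i in 1:200) {
    inst <- random_psi_instance()
    got <- compute_psi(inst$exon, index_junctions(inst$junctions))
    want <- brute_psi(inst$exon, inst$junctions)
    expect_equal(got$inclusion_reads_3ss, want$i3)
    expect_equal(got$inclusion_reads_5ss, want$i5)
    expect_equal(got$exclusion_reads, want$e)
    expect_equal(got$psi, want$psi)
    expect_equal(got$covered, want$covered)
  }
})

test_that("PSI is invariant under coordinate reflection with strand flip", {
  set.seed(77)
  M <- 100L
  for (i in 1:50) {
    inst <- random_psi_instance()
    got <- compute_psi(inst$exon, index_junctions(inst$junctions))
    ex2 <- inst$exon
    ex2$start <- M - inst$exon$end
    ex2$end <- M - inst$exon$start
    ex2$strand <- if (inst$exon$strand == "+") "-" else "+"
    j2 <- inst$junctions
    j2$start <- M - inst$junctions$end
    j2$end <- M - inst$junctions$start
    j2$strand <- ifelse(j2$strand == ".", ".",
                        ifelse(j2$strand == "+", "-", "+"))
    got2 <- compute_psi(ex2, index_junctions(j2))
    expect_equal(got2$psi3, got$psi3)
    expect_equal(got2$psi5, got$psi5)
    expect_equal(got2$psi, got$psi)
  }
})

test_that("psi_matrix emits one row per exon and sample in stable order", {
  exons <- rbind(mk_exon(1000, 1100, id = "e1"),
                 mk_exon(3000, 3100, id = "e2"))
  exons$gene_id <- c("g1", "g2")
  s1 <- mk_junctions(c(900, 1100), c(1000, 1200), c(20, 20))
  s2 <- mk_junctions(900, 1000, 15, sample_id = "s2")
  pm <- psi_matrix(exons, list(s1 = s1, s2 = s2))
  expect_equal(nrow(pm), 4L)
  expect_equal(pm$exon_id, c("e1", "e1", "e2", "e2"))
  expect_equal(pm$sample_id, c("s1", "s2", "s1", "s2"))
  # exon on a chrom absent from junction data: undefined, uncovered
  far <- mk_exon(10, 50, chrom = "cZ", id = "e3")
  far$gene_id <- "g3"
  pm2 <- psi_matrix(far, list(s1 = s1))
  expect_true(is.na(pm2$psi))
  expect_false(pm2$covered)
  # duplicate samples give identical PSI columns
  pm3 <- psi_matrix(exons, list(a = s1, b = s1))
  expect_equal(pm3$psi[pm3$sample_id == "a"], pm3$psi[pm3$sample_id == "b"])
})

test_that("delta_psi subtracts aggregated conditions and gates coverage", {
  exons <- mk_exon(1000, 1100, id = "e1")
  exons$gene_id <- "g1"
  ctrl <- mk_junctions(c(900, 1100, 850), c(1000, 1200, 1250),
                       c(95, 95, 5))
  trt <- mk_junctions(c(900, 1100, 850), c(1000, 1200, 1250),
                      c(5, 5, 95), sample_id = "t1")
  d <- delta_psi(psi_matrix(exons, list(c1 = ctrl)),
                 psi_matrix(exons, list(t1 = trt)))
  expect_equal(d$psi_control, 0.95)
  expect_equal(d$psi_treated, 0.05)
  expect_equal(d$delta_psi, -0.90)
  expect_true(d$covered_both)

  # identical groups: delta exactly zero
  d0 <- delta_psi(psi_matrix(exons, list(c1 = ctrl)),
                  psi_matrix(exons, list(c1 = ctrl)))
  expect_equal(d0$delta_psi, 0)

  # treated uncovered: record emitted, delta undefined
  thin <- mk_junctions(900, 1000, 2, sample_id = "t1")
  d1 <- delta_psi(psi_matrix(exons, list(c1 = ctrl)),
                  psi_matrix(exons, list(t1 = thin)))
  expect_false(d1$covered_both)
  expect_true(is.na(d1$delta_psi))
})

test_that("delta_psi rejects mismatched exon sets listing the missing ids", {
  e1 <- mk_exon(1000, 1100, id = "e1"); e1$gene_id <- "g"
  e2 <- mk_exon(3000, 3100, id = "e2"); e2$gene_id <- "g"
  jx <- mk_junctions(900, 1000, 20)
  expect_error(
    delta_psi(psi_matrix(e1, list(s = jx)), psi_matrix(e2, list(s = jx))),
    "e1.*|e2.*"
  )
})

test_that("pooled and per-sample-mean aggregators differ as expected", {
  exons <- mk_exon(1000, 1100, id = "e1")
  exons$gene_id <- "g1"
  # sample A deep (90/10), sample B shallow (1/1): pooled ratio vs mean
  sA <- mk_junctions(c(900, 1100, 850), c(1000, 1200, 1250), c(90, 90, 10))
  sB <- mk_junctions(c(900, 1100, 850), c(1000, 1200, 1250), c(10, 10, 10),
                     sample_id = "sB")
  pm <- psi_matrix(exons, list(sA = sA, sB = sB))
  pooled <- delta_psi(pm, pm, aggregator = "pooled")
  meaned <- delta_psi(pm, pm, aggregator = "mean")
  expect_equal(pooled$psi_control, 100 / 120)
  expect_equal(meaned$psi_control, (0.9 + 0.5) / 2)
})
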