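# Intron derivation, projection, clustering, ancestral inference, ORF
# screen.

mk_gene <- function(id, coding_lens, strand = "+") {
  starts <- cumsum(c(0, utils::head(coding_lens, -1) + 1000))
  gene_model(id, paste0("ctg_", id), strand,
             cbind(starts, starts + coding_lens))
}

test_that("intron marks carry cumulative offsets, phases and host residues", {
  m <- introns_from_gene_model(mk_gene("g", c(100, 203)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$coding_offset, 100L)
  expect_equal(m$phase, 1L)
  expect_equal(m$host_residue, 34L)

  m2 <- introns_from_gene_model(mk_gene("g", c(99, 99, 99)))
  expect_equal(m2$coding_offset, c(99L, 198L))
  expect_equal(m2$phase, c(0L, 0L))
  expect_equal(m2$host_residue, c(34L, 67L))

  expect_equal(nrow(introns_from_gene_model(mk_gene("g", 300))), 0L)
  expect_warning(introns_from_gene_model(mk_gene("g", c(100, 100))),
                 "divisible")
})

test_that("marks satisfy the phase and count invariants for random models", {
  set.seed(31)
  for (rep in 1:20) {
    n_ex <- sample(2:18, 1)
    lens <- sample(30:300, n_ex, replace = TRUE)
    lens[n_ex] <- lens[n_ex] + (3 - sum(lens) %% 3) %% 3
    m <- introns_from_gene_model(mk_gene("g", lens))
    expect_equal(nrow(m), n_ex - 1)
    expect_equal(m$phase, m$coding_offset %% 3)
    expect_equal(m$host_residue,
                 ifelse(m$phase == 0, m$coding_offset / 3 + 1,
                        m$coding_offset %/% 3 + 1))
  }
})

test_that("projection counts non-gap cells and is identity on gap-free rows", {
  aln <- protein_alignment(c(g1 = "M-KV", g2 = "MAKV"))
  marks <- data.frame(gene_id = "g1", index = 1L, coding_offset = 4L,
                      phase = 1L, host_residue = 2L)
  p <- project_introns(marks, aln)
  expect_equal(p$column, 3L)

  marks2 <- data.frame(gene_id = "g2", index = 1:3, coding_offset = c(1, 4, 10),
                       phase = c(1, 1, 1), host_residue = 1:3)
  expect_equal(project_introns(marks2, aln)$column, 1:3)

  bad <- data.frame(gene_id = "g1", index = 1, coding_offset = 31,
                    phase = 1, host_residue = 11)
  expect_error(project_introns(bad, aln), "g1.*11")
  absent <- data.frame(gene_id = "nope", index = 1, coding_offset = 4,
                       phase = 1, host_residue = 2)
  expect_error(project_introns(absent, aln), "nope")
})

pin <- function(gene, column, phase, offset = 3 * (column - 1) + phase) {
  data.frame(gene_id = gene, index = 1L, coding_offset = offset,
             phase = phase, host_residue = max(1, column), column = column)
}

test_that("clustering groups by phase and proximity", {
  two_same <- rbind(pin("a", 100, 1), pin("b", 100, 1))
  g <- cluster_homologous_introns(two_same, tau = 5)
  expect_equal(nrow(g), 1L)
  expect_equal(g$tier, "strict")
  expect_equal(g$n_members, 2L)

  diff_phase <- rbind(pin("a", 100, 0), pin("b", 100, 1))
  expect_equal(nrow(cluster_homologous_introns(diff_phase, tau = 5)), 2L)

  seven <- do.call(rbind, lapply(1:7, function(i)
    pin(paste0("g", i), 100 + (i %% 3), 2)))
  g7 <- cluster_homologous_introns(seven, tau = 5)
  expect_equal(nrow(g7), 1L)
  expect_equal(g7$n_members, 7L)
  expect_equal(g7$tier, "similar")

  expect_equal(nrow(cluster_homologous_introns(two_same[0, ], tau = 5)), 0L)
})

test_that("clustering is invariant to input order", {
  set.seed(13)
  pins <- do.call(rbind, lapply(1:15, function(i)
    pin(paste0("g", i), sample(50:70, 1), sample(0:2, 1))))
  a <- cluster_homologous_introns(pins, tau = 3)
  b <- cluster_homologous_introns(pins[sample(nrow(pins)), ], tau = 3)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("tau = 0 clustering equals exact (phase, column) grouping", {
  set.seed(97)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    pins <- do.call(rbind, lapply(seq_len(n), function(i)
      pin(paste0("g", i), sample(10:20, 1), sample(0:2, 1))))
    got <- cluster_homologous_introns(pins, tau = 0)
    oracle <- brute_force_groups(pins)
    expect_equal(nrow(got), length(oracle))
    expect_true(all(got$tier == "strict"))
    got_sets <- lapply(attr(got, "members_detail") |>
                         (\(d) split(paste(d$phase, d$column), d$group))(),
                       unique)
    expect_true(all(lengths(got_sets) == 1))
  }
})

test_that("a gene contributing two close introns forces a split at the largest gap", {
  pins <- rbind(pin("x", 100, 0), pin("y", 100, 0), pin("x", 104, 0))
  g <- cluster_homologous_introns(pins, tau = 5)
  expect_equal(nrow(g), 2L)
  expect_equal(sort(g$n_members), c(1L, 2L))
  big <- g[g$n_members == 2, ]
  expect_setequal(big$members[[1]], c("x", "y"))
  expect_equal(big$min_col, 100L)
  expect_equal(big$max_col, 100L)
})

test_that("ancestral inference keeps groups spanning all required clades", {
  pins <- rbind(
    do.call(rbind, lapply(1:16, function(i)
      rbind(pin("geneA", 10 * i, 1), pin("geneB", 10 * i + 2, 1)))),
    pin("geneA", 400, 0))  # private intron, not ancestral
  groups <- cluster_homologous_introns(pins, tau = 5)
  clades <- c(geneA = "cladeA", geneB = "cladeB")
  anc <- infer_ancestral_structure(groups, clades, c("cladeA", "cladeB"))
  expect_equal(anc$n_introns, 16L)
  expect_equal(anc$n_exons, 17L)

  none <- infer_ancestral_structure(
    cluster_homologous_introns(pin("geneA", 400, 0), tau = 5),
    clades, c("cladeA", "cladeB"))
  expect_equal(none$n_introns, 0L)
  expect_equal(none$n_exons, 1L)

  expect_error(infer_ancestral_structure(groups, clades, character(0)),
               "at least one clade")
  expect_error(infer_ancestral_structure(groups, c(geneA = "cladeA"),
                                         "cladeA"), "geneB")
})

test_that("ORF screen counts premature stops, frameshifts and missing exons", {
  r <- orf_integrity(c(ok = "ATGAAATGA"))
  expect_equal(length(r$premature_stops), 0L)
  expect_true(r$frame_ok)
  expect_equal(r$classification, "intact")

  r2 <- orf_integrity(c(one = "ATGTAAAAATGA"))
  expect_equal(r2$premature_stops, 2L)
  expect_equal(r2$classification, "suspect")

  # two premature stops plus a frameshift
  r3 <- orf_integrity(c(pg = "ATGTAAAAATAGAAAC"))
  expect_equal(r3$premature_stops, c(2L, 4L))
  expect_false(r3$frame_ok)
  expect_equal(r3$n_disruptions, 3L)
  expect_equal(r3$classification, "pseudogene")

  # missing exons count as disruptions
  r4 <- orf_integrity(c(m = "ATGAAATGA"), expected_exons = 17,
                      observed_exons = 15)
  expect_equal(r4$n_disruptions, 2L)
  expect_equal(r4$classification, "pseudogene")

  expect_error(orf_integrity(c(bad = "ATGXYZ")), "non-ACGTN")
})
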