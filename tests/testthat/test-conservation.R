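# JS conservation scoring, windowing, domain means, p-distances.

test_that("column distributions exclude gaps and X and honour pseudocounts", {
  aln <- protein_alignment(c(a = "A", b = "A", c = "A", d = "A"))
  p <- column_distribution(aln, 1, pseudocount = 1e-12)
  expect_equal(unname(p["A"]), 1, tolerance = 1e-9)

  aln2 <- protein_alignment(c(a = "A", b = "V", c = "-", d = "X"))
  p2 <- column_distribution(aln2, 1, pseudocount = 1e-12)
  expect_equal(unname(p2["A"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(p2["V"]), 0.5, tolerance = 1e-9)

  aln3 <- protein_alignment(c(a = "A", b = "A", c = "V"))
  p3 <- column_distribution(aln3, 1, pseudocount = 1e-7)
  hand <- setNames(rep(1e-7, 20), names(p3))
  hand["A"] <- 2 + 1e-7
  hand["V"] <- 1 + 1e-7
  hand <- hand / sum(hand)
  expect_equal(as.numeric(p3), as.numeric(hand), tolerance = 1e-9)

  gaps <- protein_alignment(c(a = "-A", b = "-A"))
  pg <- column_distribution(gaps, 1)
  expect_true(attr(pg, "all_gap"))
  expect_equal(as.numeric(pg), rep(1 / 20, 20))

  w <- column_distribution(aln3, 1, pseudocount = 1e-12,
                           weights = c(1, 1, 2))
  expect_equal(unname(w["V"]), 0.5, tolerance = 1e-9)
})

test_that("JS divergence matches its definition and bounds", {
  bg <- blosum62_background()
  expect_equal(js_divergence(bg, bg), 0)

  pA <- setNames(c(1, rep(0, 19)), names(bg))
  pV <- setNames(rep(0, 20), names(bg))
  pV["V"] <- 1
  expect_equal(js_divergence(pA, pV), 1)

  unif <- setNames(rep(1 / 20, 20), names(bg))
  expect_equal(js_divergence(unif, bg), naive_js(unif, bg),
               tolerance = 1e-12)

  # symmetry at lambda 0.5, identity at 0, over random draws
  set.seed(17)
  for (i in 1:25) {
    p <- random_distribution()
    q <- random_distribution()
    expect_equal(js_divergence(p, q), js_divergence(q, p),
                 tolerance = 1e-12)
    expect_equal(js_divergence(p, p), 0)
    s <- js_divergence(p, q)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
  expect_error(js_divergence(pA * 2, bg), "not a probability")
})

test_that("profiles: constant columns, window-0 identity, hand-checked windowing", {
  seqs <- setNames(rep(paste(rep("K", 6), collapse = ""), 4),
                   paste0("s", 1:4))
  aln <- protein_alignment(seqs)
  prof <- score_profile(aln, window = 3)
  pointK <- setNames(rep(1e-7, 20), names(blosum62_background()))
  pointK["K"] <- 4 + 1e-7  # 4 sequences all K, plus the pseudocount
  pointK <- pointK / sum(pointK)
  expected <- naive_js(pointK, blosum62_background())
  expect_equal(prof$raw_js, rep(expected, 6), tolerance = 1e-9)
  expect_equal(prof$windowed_js, prof$raw_js, tolerance = 1e-12)

  set.seed(23)
  aln2 <- protein_alignment(random_alignment_seqs(5, 9))
  p0 <- score_profile(aln2, window = 0)
  expect_equal(p0$windowed_js, p0$raw_js)

  # hand-computed moving average with lambda_w = 0.5, window 1
  p1 <- score_profile(aln2, window = 1, lambda_window = 0.5)
  raw <- p1$raw_js
  n <- length(raw)
  hand <- numeric(n)
  for (i in seq_len(n)) {
    neigh <- c(if (i > 1) raw[i - 1], if (i < n) raw[i + 1])
    hand[i] <- 0.5 * raw[i] + 0.5 * mean(neigh)
  }
  expect_equal(p1$windowed_js, hand, tolerance = 1e-12)
})

test_that("gap penalty multiplies raw scores by the residue fraction", {
  aln <- protein_alignment(c(a = "KK", b = "KK", c = "K-", d = "K-"))
  on <- score_profile(aln, window = 0, gap_penalty = TRUE)
  off <- score_profile(aln, window = 0, gap_penalty = FALSE)
  expect_equal(on$raw_js[2], off$raw_js[2] * 0.5, tolerance = 1e-12)
  expect_equal(on$gap_fraction, c(0, 0.5))
})

test_that("domain means drop gap columns and include an All row", {
  set.seed(41)
  seqs <- random_alignment_seqs(4, 20)
  aln <- protein_alignment(seqs)
  prof <- score_profile(aln, window = 2)
  dmap <- domain_map(c("D1", "D2"), c(1, 11), c(10, 20),
                     "alignment_columns")
  dm <- domain_mean(prof, aln, dmap)
  expect_equal(dm$name, c("All", "D1", "D2"))
  expect_equal(dm$ungapped_length, c(20L, 10L, 10L))
  # brute-force column averages on a gap-free alignment
  expect_equal(dm$mean_js[1], mean(prof$windowed_js), tolerance = 1e-12)
  expect_equal(dm$mean_js[2], mean(prof$windowed_js[1:10]),
               tolerance = 1e-12)

  # punch gaps into 3 columns of D1 (any sequence gapped drops the column)
  mat <- aln$mat
  mat["s01", 2] <- "-"
  mat["s02", 5] <- "-"
  mat["s03", 9] <- "-"
  aln_g <- protein_alignment(setNames(apply(mat, 1, paste, collapse = ""),
                                      rownames(mat)))
  prof_g <- score_profile(aln_g, window = 2)
  dm_g <- domain_mean(prof_g, aln_g, dmap)
  expect_equal(dm_g$ungapped_length, c(17L, 7L, 10L))
  keep <- setdiff(1:10, c(2, 5, 9))
  expect_equal(dm_g$mean_js[2], mean(prof_g$windowed_js[keep]),
               tolerance = 1e-12)

  # a domain with no gap-free column reports NA / 0
  mat2 <- aln$mat
  mat2["s01", 11:20] <- "-"
  aln_z <- protein_alignment(setNames(apply(mat2, 1, paste, collapse = ""),
                                      rownames(mat2)))
  dm_z <- domain_mean(score_profile(aln_z, window = 0), aln_z, dmap)
  expect_true(is.na(dm_z$mean_js[3]))
  expect_equal(dm_z$ungapped_length[3], 0L)
})

test_that("p-distance counts differing comparable sites", {
  expect_equal(p_distance("MKVL", "MKVL"), 0)
  expect_equal(p_distance("MKVL", "MKIL"), 0.25)
  expect_equal(p_distance("MK-L", "MKIL"), 0)
  expect_equal(p_distance("MKXL", "MKIL"), 0)
  expect_error(p_distance("--", "AA"), "no comparable")
  expect_error(p_distance("AAA", "AA"), "equal aligned length")
})

test_that("p-distance matrices are symmetric, zero-diagonal and match ape", {
  set.seed(53)
  seqs <- random_alignment_seqs(6, 40)
  aln <- protein_alignment(seqs)
  m <- pdistance_matrix(aln)$All
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  expect_true(all(m >= 0 & m <= 1))

  ref <- as.matrix(ape::dist.aa(ape::as.AAbin(aln$mat), scaled = TRUE))
  expect_equal(m, ref[rownames(m), colnames(m)], tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical records give a zero matrix
  z <- pdistance_matrix(protein_alignment(c(a = "MKVL", b = "MKVL")))$All
  expect_equal(unname(z), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("complete deletion removes alignment-wide gap columns first", {
  aln <- protein_alignment(c(a = "MKVL", b = "MKIL", c = "M-VL"))
  pw <- pdistance_matrix(aln, deletion = "pairwise")$All
  co <- pdistance_matrix(aln, deletion = "complete")$All
  expect_equal(pw["a", "b"], 0.25)   # 4 comparable sites
  expect_equal(co["a", "b"], 1 / 3)  # column 2 dropped for everyone
})

test_that("per-domain matrices accompany the whole-protein matrix", {
  set.seed(59)
  aln <- protein_alignment(random_alignment_seqs(4, 30))
  dmap <- domain_map(c("N", "C"), c(1, 16), c(15, 30),
                     "alignment_columns")
  ms <- pdistance_matrix(aln, dmap)
  expect_equal(names(ms), c("All", "N", "C"))
  hand <- p_distance(aln$mat["s01", ], aln$mat["s02", ], cols = 16:30)
  expect_equal(ms$C["s01", "s02"], hand)
})

test_that("p-distance is a metric on gap-free sequences", {
  set.seed(61)
  for (i in 1:30) {
    s <- random_alignment_seqs(3, 25)
    d12 <- p_distance(s[1], s[2])
    d13 <- p_distance(s[1], s[3])
    d23 <- p_distance(s[2], s[3])
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_lte(d23, d12 + d13 + 1e-12)
  }
})

test_that("mean JS conservation falls as the substitution rate rises", {
  # paired design: every rate setting reuses the same seed, hence the same
  # species tree, so the only systematic difference is the rate
  rates <- seq(0.25, 5, length.out = 20)
  means <- vapply(seq_along(rates), function(i) {
    layout <- data.frame(name = "D", length = 300L)
    cfg <- sim_config(n_species = 6, domain_layout = layout,
                      rate_multiplier = list(parA = c(D = rates[i]),
                                             parB = c(D = rates[i])),
                      intron_plan = data.frame(coding_offset = integer(0),
                                               phase = integer(0)),
                      seed = 500)
    fam <- simulate_family(cfg)
    prof <- score_profile(fam$alignment, window = 3)
    mean(prof$windowed_js)
  }, 0)
  expect_lt(cor(rates, means, method = "spearman"), -0.9)
})
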