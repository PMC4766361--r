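# Paralog contrast, consensus matrices, residue-state reports, NJ trees,
# bootstrap support.

mk_table <- function(names, means) {
  data.frame(name = names, mean_js = means,
             ungapped_length = rep(10L, length(names)))
}

test_that("the contrast flags the less conserved paralog per domain", {
  tA <- mk_table(c("LID", "DCD"), c(0.82599, 0.81806))
  tB <- mk_table(c("LID", "DCD"), c(0.84046, 0.80635))
  tBoth <- mk_table(c("LID", "DCD"), c(0.79199, 0.77976))
  ct <- contrast_domains(tA, tB, tBoth)
  expect_equal(ct$less_conserved, c("A", "B"))
  expect_equal(ct$delta, tA$mean_js - tB$mean_js)

  # antisymmetry under swapping the groups
  ct_sw <- contrast_domains(tB, tA, tBoth)
  expect_equal(ct_sw$less_conserved, c("B", "A"))
  expect_equal(ct_sw$delta, -ct$delta)

  tie <- contrast_domains(tA, tA, tA)
  expect_true(all(tie$less_conserved == "tie"))

  expect_error(contrast_domains(tA, mk_table("LID", 0.5), tBoth),
               "domain sets differ.*DCD")
})

test_that("consensus matrices count residues and classify them chemically", {
  seqs <- setNames(c(rep("KD", 6), rep("KE", 4)), paste0("s", 1:10))
  aln <- protein_alignment(seqs)
  cm <- consensus_matrix(aln)
  expect_equal(unname(cm$freq[1, "K"]), 1.0)
  expect_equal(cm$consensus[1], "K")
  expect_equal(cm$consensus_class[1], "basic")
  expect_equal(unname(cm$freq[2, "D"]), 0.6)
  expect_equal(unname(cm$freq[2, "E"]), 0.4)
  expect_equal(cm$consensus[2], "D")
  expect_equal(cm$consensus_class[2], "acidic")
  expect_equal(unname(rowSums(cm$freq)), c(1, 1))

  # the chemical classes partition the 20 amino acids exactly once
  cls <- aa_chemical_class()
  expect_setequal(names(cls), mondoevo:::AA20)
  tab <- table(cls)
  expect_equal(as.integer(tab[c("polar", "basic", "acidic",
                                "hydrophobic")]), c(7L, 3L, 2L, 8L))
  expect_equal(sum(tab), 20L)

  # ties break alphabetically and are flagged
  aln_t <- protein_alignment(c(a = "D", b = "E"))
  cmt <- consensus_matrix(aln_t)
  expect_true(cmt$tie[1])
  expect_equal(cmt$consensus[1], "D")

  # gaps: excluded from the numerator, denominator choice documented
  aln_g <- protein_alignment(c(a = "K", b = "K", c = "-", d = "-"))
  expect_equal(unname(consensus_matrix(aln_g)$freq[1, "K"]), 0.5)
  expect_equal(unname(consensus_matrix(aln_g,
                                       denominator = "nongap")$freq[1, "K"]),
               1.0)
  expect_error(consensus_matrix(aln_g, cols = integer(0)), "empty")
})

test_that("residue-state reports mirror clade-level start-codon conservation", {
  seqs <- c(mam1 = "MKV", mam2 = "MKV", mam3 = "MKV",
            fish1 = "IKV", fish2 = "IKV")
  aln <- protein_alignment(seqs)
  clades <- c(mam1 = "mammal", mam2 = "mammal", mam3 = "mammal",
              fish1 = "fish", fish2 = "fish")
  rep1 <- residue_state_report(aln, "mam1", 1, "M", clades)
  expect_equal(rep1$column, 1L)
  expect_true(rep1$clade_conserved[["mammal"]])
  expect_false(rep1$clade_conserved[["fish"]])
  expect_equal(nrow(rep1$states), 5L)
  expect_setequal(rep1$states$id, aln$ids)

  # all sequences share the state -> every clade conserved
  rep2 <- residue_state_report(aln, "mam1", 2, "K", clades)
  expect_true(all(rep2$clade_conserved))

  # a gap at the column is reported as '-' and breaks conservation
  seqs_g <- c(mam1 = "MKV", mam2 = "M-V", fish1 = "MKV")
  alng <- protein_alignment(seqs_g)
  cl <- c(mam1 = "mammal", mam2 = "mammal", fish1 = "fish")
  rep3 <- residue_state_report(alng, "mam1", 2, "K", cl)
  expect_equal(rep3$states$residue[rep3$states$id == "mam2"], "-")
  expect_false(rep3$clade_conserved[["mammal"]])
})

test_that("3-taxon NJ solves the three-point equations exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  term <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(term[c("a", "b", "c")], c(a = 1, b = 2, c = 3))

  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d_bad <- d
  d_bad[1, 2] <- 99
  expect_error(nj_tree(d_bad), "symmetric")
})

test_that("NJ recovers the true split of an additive 4-taxon matrix", {
  tr0 <- ape::read.tree(text = "((a:1,b:2):3,(c:1.5,d:2.5):1);")
  d <- cophenetic(tr0)
  tr <- nj_tree(d[letters[1:4], letters[1:4]])
  expect_equal(phangorn::RF.dist(ape::unroot(tr0), tr), 0)
})

test_that("NJ separates the two paralog clades of a simulated family", {
  cfg <- small_family_cfg(seed = 71)
  fam <- simulate_family(cfg)
  m <- pdistance_matrix(fam$alignment)$All
  tr <- nj_tree(m)
  b_tips <- names(fam$clade_of)[fam$clade_of == "parB"]
  a_tips <- setdiff(tr$tip.label, b_tips)
  rooted <- ape::root(tr, outgroup = a_tips[1], resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, b_tips))
})

test_that("bootstrap support is reproducible and sensible", {
  cfg <- small_family_cfg(seed = 73)
  fam <- simulate_family(cfg)
  one <- bootstrap_support(fam$alignment, n_reps = 1, seed = 9)
  expect_true(all(one$node.label %in% c(0, 1)))

  b1 <- bootstrap_support(fam$alignment, n_reps = 25, seed = 9)
  b2 <- bootstrap_support(fam$alignment, n_reps = 25, seed = 9)
  expect_identical(b1$node.label, b2$node.label)

  # the deep split between the paralog clades is strongly supported
  split_support <- function(tr, tips) {
    for (set in list(tips, setdiff(tr$tip.label, tips))) {
      nd <- ape::getMRCA(tr, set)
      desc <- ape::extract.clade(tr, nd)$tip.label
      if (setequal(desc, set))
        return(as.numeric(tr$node.label[nd - length(tr$tip.label)]))
    }
    NA_real_
  }
  b_tips <- names(fam$clade_of)[fam$clade_of == "parB"]
  expect_gte(split_support(b1, b_tips), 0.95)
})
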