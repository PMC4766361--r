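# Independent oracles and small generators shared across tests.  Oracles
# are deliberately naive (scalar loops, brute-force enumeration) and stay
# independent of the package's own code paths.

# direct-sum Jensen-Shannon divergence, scalar loop, base-2 logs
naive_js <- function(p, q, lambda = 0.5) {
  p <- unname(p)
  q <- unname(q)
  r <- lambda * p + (1 - lambda) * q
  acc <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) acc <- acc + lambda * p[i] * log2(p[i] / r[i])
    if (q[i] > 0) acc <- acc + (1 - lambda) * q[i] * log2(q[i] / r[i])
  }
  acc
}

# random probability 20-vector
random_distribution <- function() {
  x <- stats::rexp(20)
  p <- x / sum(x)
  names(p) <- mondoevo:::AA20
  p
}

# exact grouping by (phase, column): the tau = 0 clustering oracle,
# checked pairwise (two introns share a group iff phase and column match)
brute_force_groups <- function(pins) {
  key <- paste(pins$phase, pins$column)
  split(seq_len(nrow(pins)), key)
}

# random gap-free protein alignment as a named character vector
random_alignment_seqs <- function(n_seq, n_col, gap_prob = 0) {
  aas <- mondoevo:::AA20
  vapply(seq_len(n_seq), function(i) {
    chars <- sample(aas, n_col, replace = TRUE)
    if (gap_prob > 0)
      chars[stats::runif(n_col) < gap_prob] <- "-"
    paste(chars, collapse = "")
  }, "") |>
    stats::setNames(sprintf("s%02d", seq_len(n_seq)))
}

# a small two-paralog study configuration used by several tests
small_family_cfg <- function(seed = 7, ...) {
  layout <- data.frame(name = c("D1", "D2", "D3"),
                       length = c(60L, 50L, 40L))
  plan <- data.frame(coding_offset = c(100L, 250L, 341L))
  plan$phase <- plan$coding_offset %% 3
  sim_config(n_species = 6, domain_layout = layout, intron_plan = plan,
             seed = seed, ...)
}

tmpfile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
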