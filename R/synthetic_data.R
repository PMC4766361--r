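# Synthetic paralog families with known ground truth.  The generator
# emulates the study design the analysis modules are built for: a
# duplicated gene family across ~10 species, per-domain substitution-rate
# multipliers that differ between the paralogs, a conserved intron
# architecture with optional loss, and occasional ORF-disrupting mutations.

#' Default domain layout for simulated families
#'
#' A Mondo-like architecture: an N-terminal extension carrying a
#' low-glucose inhibitory (LID) and glucose-response activation (GRACE)
#' region, a proline-rich middle, and C-terminal bHLH-Zip and
#' dimerization/cytoplasmic-localization (DCD) domains, separated by
#' unnamed linkers; 852 residues in total.
#'
#' @return Data frame with columns `name`, `length` (residues).
#' @export
default_domain_layout <- function() {
  data.frame(
    name = c("Nterm", "LID", "GRACE", "linker1", "Pro-rich",
             "linker2", "bHLH-Zip", "linker3", "DCD", "Cterm"),
    length = c(37L, 157L, 80L, 58L, 209L, 120L, 61L, 86L, 41L, 3L),
    stringsAsFactors = FALSE)
}

#' Default intron plan for simulated families
#'
#' Sixteen introns (17 coding exons) spread over the coding sequence with
#' mixed phases; offsets are coding nucleotides 5' of each junction.
#'
#' @return Data frame with columns `coding_offset`, `phase`.
#' @export
default_intron_plan <- function() {
  offs <- c(100L, 247L, 398L, 451L, 620L, 787L, 929L, 1088L, 1235L,
            1379L, 1523L, 1700L, 1831L, 2009L, 2185L, 2342L)
  data.frame(coding_offset = offs, phase = as.integer(offs %% 3))
}

#' Simulation configuration
#'
#' Defines the conditions of a simulated duplicated-family study.  The
#' defaults mirror the study design the analysis targets: 10 species each
#' carrying one intact copy of both paralogs, a duplication preceding the
#' species radiation (long paralog stems, shallow crown), a conserved
#' 16-intron architecture, and no structural change.
#'
#' @param n_species number of species.
#' @param tree_height root-to-tip height of the (ultrametric) species
#'   tree, in expected substitutions per site at rate multiplier 1.
#' @param duplication_at_root the family duplicates before the species
#'   radiation (the only mode implemented; kept explicit for clarity).
#' @param duplication_stem branch length from the duplication to each
#'   paralog's crown root, in expected substitutions per site.
#' @param domain_layout ordered data frame `(name, length)` partitioning
#'   the protein.
#' @param rate_multiplier named list keyed by paralog name, each element a
#'   named vector of per-domain multipliers; unlisted domains default
#'   to 1.
#' @param intron_plan data frame `(coding_offset, phase)` of ancestral
#'   introns; phases must equal `coding_offset %% 3`.
#' @param intron_loss_prob per-branch probability that a present intron is
#'   lost on that branch.
#' @param pseudogene_prob per-gene probability of receiving ORF-disrupting
#'   mutations (two in-frame stops plus a 1-nt deletion).
#' @param indel_rate per-site deletion probability per unit branch length
#'   (deletions only; intron host residues are never deleted so projection
#'   ground truth stays exact).
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @param paralog_names labels of the two paralog copies.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 10L,
                       tree_height = 0.15,
                       duplication_at_root = TRUE,
                       duplication_stem = 0.4,
                       domain_layout = default_domain_layout(),
                       rate_multiplier = list(),
                       intron_plan = default_intron_plan(),
                       intron_loss_prob = 0,
                       pseudogene_prob = 0,
                       indel_rate = 0,
                       seed = 1L,
                       paralog_names = c("parA", "parB")) {
  stopifnot(n_species >= 2, tree_height > 0, duplication_stem >= 0,
            intron_loss_prob >= 0, intron_loss_prob <= 1,
            pseudogene_prob >= 0, pseudogene_prob <= 1, indel_rate >= 0,
            length(paralog_names) == 2)
  if (!duplication_at_root)
    stop("only duplication at the root of the species tree is implemented")
  if (any(domain_layout$length < 1) || anyDuplicated(domain_layout$name))
    stop("invalid domain layout")
  total_nt <- 3 * sum(domain_layout$length)
  ip <- intron_plan
  if (nrow(ip)) {
    if (any(ip$phase != ip$coding_offset %% 3))
      stop("intron phases inconsistent with coding offsets")
    if (any(ip$coding_offset <= 0) || any(ip$coding_offset >= total_nt))
      stop("intron offsets must lie strictly inside the coding sequence")
    if (any(diff(ip$coding_offset) <= 0))
      stop("intron offsets must be strictly increasing")
  }
  bad_par <- setdiff(names(rate_multiplier), paralog_names)
  if (length(bad_par))
    stop("rate multipliers for unknown paralog(s): ",
         paste(bad_par, collapse = ", "))
  mult <- matrix(1, nrow = 2, ncol = nrow(domain_layout),
                 dimnames = list(paralog_names, domain_layout$name))
  for (p in names(rate_multiplier)) {
    v <- rate_multiplier[[p]]
    bad <- setdiff(names(v), domain_layout$name)
    if (length(bad))
      stop("rate multipliers for unknown domain(s): ",
           paste(bad, collapse = ", "))
    if (any(v < 0)) stop("rate multipliers must be non-negative")
    mult[p, names(v)] <- v
  }
  structure(list(n_species = as.integer(n_species),
                 tree_height = tree_height,
                 duplication_at_root = duplication_at_root,
                 duplication_stem = duplication_stem,
                 domain_layout = domain_layout,
                 rate_multiplier = mult, intron_plan = ip,
                 intron_loss_prob = intron_loss_prob,
                 pseudogene_prob = pseudogene_prob,
                 indel_rate = indel_rate, seed = as.integer(seed),
                 paralog_names = paralog_names),
            class = "sim_config")
}

# one replacement sweep: sites with >= 1 pending event draw a new residue
# from the background excluding the current one
.evolve_seq <- function(codes, blen, mult_site, bg) {
  k <- rpois(length(codes), blen * mult_site)
  rounds <- if (any(k > 0)) max(k) else 0
  for (r in seq_len(rounds)) {
    idx <- which(k >= r)
    cand <- sample.int(20, length(idx), replace = TRUE, prob = bg)
    while (any(same <- cand == codes[idx])) {
      cand[same] <- sample.int(20, sum(same), replace = TRUE, prob = bg)
    }
    codes[idx] <- cand
  }
  list(codes = codes, events = k)
}

# preorder edge indices of an ape tree (parent before child)
.preorder_edges <- function(tr) {
  ape::reorder.phylo(tr, "cladewise")$edge
}

#' Simulate a duplicated gene family with ground truth
#'
#' Draws an ultrametric coalescent species tree scaled to
#' `cfg$tree_height`, samples one ancestral protein from the BLOSUM62
#' background, duplicates it at the root and evolves each paralog copy
#' independently down the tree under a Poisson replacement process whose
#' per-site intensity is branch length times the site's (paralog, domain)
#' rate multiplier.  Introns from `cfg$intron_plan` are carried by every
#' gene and lost per branch with `intron_loss_prob`; deletions (when
#' `indel_rate > 0`) leave gaps in the true alignment; with
#' `pseudogene_prob` a gene's coding sequence receives two in-frame stop
#' codons plus a single-nucleotide deletion.
#'
#' @param cfg a [sim_config()].
#' @return List of class `sim_family`: `config`, `species_tree`,
#'   `alignment` (true [protein_alignment()]), `proteins`, `cds`
#'   ([seq_set()]s), `gene_models`, `domain_map` (alignment columns),
#'   `clade_of` (gene id to paralog), and `truth` (intron presence matrix,
#'   per-(paralog, domain) realized substitution counts, tree length per
#'   paralog, pseudogene labels, deleted-site sets, true intron columns).
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  bg <- blosum62_background()
  L <- sum(cfg$domain_layout$length)
  site_domain <- rep(cfg$domain_layout$name, cfg$domain_layout$length)
  mult_site <- lapply(cfg$paralog_names, function(p)
    as.numeric(cfg$rate_multiplier[p, site_domain]))
  names(mult_site) <- cfg$paralog_names

  tr <- ape::rcoal(cfg$n_species,
                   tip.label = sprintf("sp%02d", seq_len(cfg$n_species)))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (cfg$tree_height / depth)

  anc <- sample.int(20, L, replace = TRUE, prob = bg)
  n_tip <- length(tr$tip.label)
  n_intron <- nrow(cfg$intron_plan)
  edges <- .preorder_edges(tr)
  edge_len <- tr$edge.length[match(paste(edges[, 1], edges[, 2]),
                                   paste(tr$edge[, 1], tr$edge[, 2]))]

  host_of <- function(off, phase)
    as.integer(ifelse(phase == 0, off / 3 + 1, off %/% 3 + 1))
  hosts <- if (n_intron)
    host_of(cfg$intron_plan$coding_offset, cfg$intron_plan$phase)
  else integer(0)

  sim_one_paralog <- function(pname) {
    ms <- mult_site[[pname]]
    # stem from the duplication down to the paralog crown root
    st <- .evolve_seq(anc, cfg$duplication_stem, ms, bg)
    events <- st$events
    nslot <- n_tip + tr$Nnode
    seqs <- vector("list", nslot)
    pres <- vector("list", nslot)
    dele <- vector("list", nslot)
    root <- n_tip + 1L
    seqs[[root]] <- st$codes
    pres[[root]] <- rep(TRUE, n_intron)
    dele[[root]] <- rep(FALSE, L)
    lose <- function(p, blen)
      p & (runif(length(p)) >= cfg$intron_loss_prob)
    del_step <- function(d, blen) {
      if (cfg$indel_rate == 0) return(d)
      hit <- runif(L) < pmin(1, cfg$indel_rate * blen)
      hit[hosts] <- FALSE  # intron host residues are never deleted
      d | hit
    }
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; chd <- edges[e, 2]; bl <- edge_len[e]
      ev <- .evolve_seq(seqs[[par]], bl, ms, bg)
      seqs[[chd]] <- ev$codes
      events <- events + ev$events
      pres[[chd]] <- lose(pres[[par]], bl)
      dele[[chd]] <- del_step(dele[[par]], bl)
    }
    list(tip_seqs = seqs[seq_len(n_tip)],
         tip_pres = pres[seq_len(n_tip)],
         tip_dele = dele[seq_len(n_tip)],
         events = events,
         tree_length = cfg$duplication_stem + sum(tr$edge.length))
  }

  sims <- lapply(cfg$paralog_names, sim_one_paralog)
  names(sims) <- cfg$paralog_names

  gene_ids <- as.vector(t(outer(tr$tip.label, cfg$paralog_names, paste,
                                sep = "_")))
  clade_of <- setNames(rep(cfg$paralog_names, times = cfg$n_species),
                       gene_ids)

  aligned <- character(0)
  cds <- character(0)
  proteins <- character(0)
  models <- list()
  presence <- matrix(FALSE, nrow = length(gene_ids), ncol = n_intron,
                     dimnames = list(gene_ids, NULL))
  deleted <- list()
  codon_choices <- .codons_by_aa()
  pseudo <- setNames(rep(FALSE, length(gene_ids)), gene_ids)

  for (sp_i in seq_len(n_tip)) {
    for (pname in cfg$paralog_names) {
      gid <- paste(tr$tip.label[sp_i], pname, sep = "_")
      sim <- sims[[pname]]
      codes <- sim$tip_seqs[[sp_i]]
      del <- sim$tip_dele[[sp_i]]
      chars <- AA20[codes]
      chars[del] <- "-"
      aligned[gid] <- paste(chars, collapse = "")
      prot <- AA20[codes[!del]]
      proteins[gid] <- paste(prot, collapse = "")
      # back-translate with uniformly drawn synonymous codons
      cds_codons <- vapply(prot, function(a) {
        cs <- codon_choices[[a]]
        cs[sample.int(length(cs), 1)]
      }, "")
      cds_seq <- paste(cds_codons, collapse = "")
      pres <- sim$tip_pres[[sp_i]]
      presence[gid, ] <- pres
      deleted[[gid]] <- which(del)
      # intron offsets in this gene's own coding coordinates: hosts are
      # re-ranked over surviving residues
      offs <- integer(0)
      if (n_intron && any(pres)) {
        surv_rank <- cumsum(!del)
        h2 <- surv_rank[hosts[pres]]
        offs <- 3L * (h2 - 1L) + cfg$intron_plan$phase[pres]
        offs <- offs[offs > 0 & offs < 3L * length(prot)]
      }
      if (cfg$pseudogene_prob > 0 &&
          runif(1) < cfg$pseudogene_prob) {
        pseudo[gid] <- TRUE
        cds_seq <- .disrupt_orf(cds_seq)
      }
      cds[gid] <- cds_seq
      models[[gid]] <- .gene_model_from_offsets(gid, offs, nchar(cds_seq))
    }
  }

  realized <- do.call(rbind, lapply(cfg$paralog_names, function(p)
    tapply(sims[[p]]$events, factor(site_domain,
                                    levels = cfg$domain_layout$name), sum)))
  rownames(realized) <- cfg$paralog_names

  ends <- cumsum(cfg$domain_layout$length)
  dmap <- domain_map(cfg$domain_layout$name, ends - cfg$domain_layout$length + 1,
                     ends, "alignment_columns")

  structure(list(
    config = cfg,
    species_tree = tr,
    alignment = protein_alignment(aligned),
    proteins = seq_set(proteins, "protein"),
    cds = seq_set(cds, "dna"),
    gene_models = models,
    domain_map = dmap,
    clade_of = clade_of,
    truth = list(
      intron_plan = cfg$intron_plan,
      intron_presence = presence,
      intron_true_columns = hosts,  # no insertions: column == ancestral index
      realized_subs = realized,
      tree_length = vapply(sims, function(s) s$tree_length, 0),
      pseudogene = pseudo,
      deleted_sites = deleted,
      n_ancestral_introns = n_intron)),
    class = "sim_family")
}

# genomic gene model on one synthetic contig; fixed 1-kb introns
.gene_model_from_offsets <- function(gid, offs, total_nt) {
  offs <- offs[offs < total_nt]
  lens <- diff(c(0L, offs, total_nt))
  starts <- cumsum(c(0L, utils::head(lens, -1) + 1000L))
  gene_model(gid, paste0("ctg_", gid), "+",
             cbind(starts, starts + lens))
}

.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA20]
}

# two in-frame premature stops plus a terminal 1-nt deletion: always >= 2
# ORF disruptions, guaranteeing a pseudogene call
.disrupt_orf <- function(cds_seq) {
  k <- nchar(cds_seq) %/% 3
  at <- unique(pmax(1, c(k %/% 4, k %/% 2)))
  for (cpos in at) {
    substr(cds_seq, 3 * cpos - 2, 3 * cpos) <- "TAA"
  }
  substr(cds_seq, 1, nchar(cds_seq) - 1)
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("<sim_family> %d species x 2 paralogs, %d columns, %d ancestral intron(s)\n",
              x$config$n_species, x$alignment$ncols,
              x$truth$n_ancestral_introns))
  invisible(x)
}

#' Write a simulated family bundle to a directory
#'
#' Emits `cds.fasta`, `proteins.fasta`, `alignment.fasta`,
#' `gene_models.gff3`, `gene_models.tsv`, `domain_map.tsv`,
#' `species_tree.nwk` and ground-truth TSVs (`truth_intron_presence.tsv`,
#' `truth_realized_subs.tsv`, `truth_labels.tsv`) plus a flat `config.txt`
#' parameter manifest.  Output is a deterministic function of the bundle.
#'
#' @param fam a [simulate_family()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_fasta(fam$cds, fp("cds.fasta"))
  write_fasta(fam$proteins, fp("proteins.fasta"))
  aligned <- apply(fam$alignment$mat, 1, paste, collapse = "")
  write_fasta(setNames(aligned, fam$alignment$ids), fp("alignment.fasta"))
  write_gene_models(fam$gene_models, fp("gene_models.gff3"), "gff3")
  write_gene_models(fam$gene_models, fp("gene_models.tsv"), "simple_tsv")
  write_domain_map(fam$domain_map, fp("domain_map.tsv"))
  write_newick(fam$species_tree, fp("species_tree.nwk"))
  pres <- data.frame(gene_id = rownames(fam$truth$intron_presence),
                     fam$truth$intron_presence + 0, check.names = FALSE)
  names(pres)[-1] <- paste0("intron", seq_len(ncol(pres) - 1))
  write.table(pres, fp("truth_intron_presence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rs <- data.frame(paralog = rownames(fam$truth$realized_subs),
                   fam$truth$realized_subs, check.names = FALSE)
  write.table(rs, fp("truth_realized_subs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lab <- data.frame(gene_id = names(fam$truth$pseudogene),
                    paralog = unname(fam$clade_of[names(fam$truth$pseudogene)]),
                    pseudogene = unname(fam$truth$pseudogene))
  write.table(lab, fp("truth_labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- fam$config
  manifest <- c(
    sprintf("n_species=%d", cfg$n_species),
    sprintf("tree_height=%g", cfg$tree_height),
    sprintf("duplication_stem=%g", cfg$duplication_stem),
    sprintf("intron_loss_prob=%g", cfg$intron_loss_prob),
    sprintf("pseudogene_prob=%g", cfg$pseudogene_prob),
    sprintf("indel_rate=%g", cfg$indel_rate),
    sprintf("seed=%d", cfg$seed),
    sprintf("paralogs=%s", paste(cfg$paralog_names, collapse = ",")),
    sprintf("rate_multiplier[%s,%s]=%g",
            rep(rownames(cfg$rate_multiplier),
                ncol(cfg$rate_multiplier)),
            rep(colnames(cfg$rate_multiplier),
                each = nrow(cfg$rate_multiplier)),
            as.vector(cfg$rate_multiplier)))
  writeLines(manifest, fp("config.txt"))
  invisible(dir)
}
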