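#' Configuration for the synthetic OVX-like study generator
#'
#' Bundles every parameter of [simulate_dataset()]. Defaults emulate the
#' profiled study conditions: 3 ovariectomized vs 3 sham-operated samples,
#' negative-binomial RNA-seq counts for circRNAs and mRNAs, log-normal
#' microarray intensities for miRNAs, planted differential expression clearing
#' the fold-change >= 1.5 filter, and planted seed-complementary MREs wired
#' into sponge-consistent ceRNA circuits (circRNA and mRNA moving together,
#' their shared miRNA moving opposite).
#'
#' @param n_case,n_control Samples per group (default 3 and 3).
#' @param n_circ,n_mirna,n_mrna Feature counts per class (defaults 60/40/600,
#'   the same order as the differential-expression tables of the emulated
#'   study at desk scale).
#' @param n_circuits Number of planted ceRNA circuits (disjoint
#'   circRNA/miRNA/mRNA triples; default 4). Must be <= min of the class sizes.
#' @param n_extra_de_circ,n_extra_de_mirna,n_extra_de_mrna Additional
#'   differentially expressed features planted outside any circuit (no planted
#'   binding sites). Defaults 16/18/76, so the total DE features (20/22/80)
#'   match the scale of the emulated study -- in particular 22 DE miRNAs, the
#'   universe of the hypergeometric ceRNA score.
#' @param lfc_de Planted |log2 fold change| of DE features, default 1.5
#'   (>= log2(1.5) so planted features clear the fold-change filter in
#'   expectation). Set 0 for a fully null simulation.
#' @param nb_dispersion Negative-binomial dispersion alpha in
#'   Var = mu + alpha * mu^2 (default 0.1).
#' @param base_mean_log,base_mean_sd Mean and SD of the natural-log baseline
#'   expression of count features (defaults 6 and 1, i.e. typical means of
#'   ~400 counts).
#' @param intensity_base,intensity_base_sd Mean and SD of baseline miRNA
#'   log2 intensities (defaults 8 and 1.5).
#' @param intensity_sd Residual SD of miRNA log2 intensities (default 0.25).
#' @param sponge_rho Fraction of each circuit member's biological variance
#'   carried by the circuit's shared per-sample sponge factor (default 0.95).
#'   The factor enters the log-scale mean with positive sign for the circRNA
#'   and mRNA and negative sign for the miRNA, and the member's residual
#'   dispersion is reduced so its marginal dispersion stays at
#'   `nb_dispersion` (see the methods vignette).
#' @param mirna_len Length of simulated mature miRNAs (default 22 nt).
#' @param len_circ,len_mrna Lengths of circRNA junction pseudo-sequences and
#'   mRNA target sequences (defaults 400 and 500 nt).
#' @param seed_len Planted-site length: the site is the exact reverse
#'   complement of miRNA positions 2..(1+seed_len). Default 21, the full
#'   complement of positions 2-22 of a 22-nt miRNA, so planted sites exceed
#'   the default alignment-score and energy thresholds of [predict_mres()].
#' @param sf_range Range of simulated library size factors, drawn
#'   log-uniformly (default c(0.7, 1.4)).
#' @param n_sets Number of synthetic annotation gene sets (default 20; the
#'   first set contains all circuit mRNAs).
#' @param seed RNG seed (default 1).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_case = 3, n_control = 3,
                              n_circ = 60, n_mirna = 40, n_mrna = 600,
                              n_circuits = 4,
                              n_extra_de_circ = 16, n_extra_de_mirna = 18,
                              n_extra_de_mrna = 76,
                              lfc_de = 1.5, nb_dispersion = 0.1,
                              base_mean_log = 6, base_mean_sd = 1,
                              intensity_base = 8, intensity_base_sd = 1.5,
                              intensity_sd = 0.25,
                              sponge_rho = 0.95,
                              mirna_len = 22, len_circ = 400, len_mrna = 500,
                              seed_len = 21, sf_range = c(0.7, 1.4),
                              n_sets = 20, seed = 1) {
  cfg <- list(n_case = n_case, n_control = n_control, n_circ = n_circ,
              n_mirna = n_mirna, n_mrna = n_mrna, n_circuits = n_circuits,
              n_extra_de_circ = n_extra_de_circ,
              n_extra_de_mirna = n_extra_de_mirna,
              n_extra_de_mrna = n_extra_de_mrna,
              lfc_de = lfc_de, nb_dispersion = nb_dispersion,
              base_mean_log = base_mean_log, base_mean_sd = base_mean_sd,
              intensity_base = intensity_base,
              intensity_base_sd = intensity_base_sd,
              intensity_sd = intensity_sd, sponge_rho = sponge_rho,
              mirna_len = mirna_len, len_circ = len_circ, len_mrna = len_mrna,
              seed_len = seed_len, sf_range = sf_range, n_sets = n_sets,
              seed = seed)
  with(cfg, {
    stopifnot(n_case >= 1, n_control >= 1, n_circ >= 1, n_mirna >= 1,
              n_mrna >= 1, n_circuits >= 0, lfc_de >= 0, nb_dispersion >= 0,
              intensity_sd > 0, sponge_rho >= 0, sponge_rho < 1,
              mirna_len >= 9, seed_len >= 0, seed_len <= mirna_len - 1,
              n_sets >= 1, length(sf_range) == 2, all(sf_range > 0))
    if (n_circuits > min(n_circ, n_mirna, n_mrna))
      stop("n_circuits must be <= min(n_circ, n_mirna, n_mrna)", call. = FALSE)
    if (n_circuits + n_extra_de_circ > n_circ ||
        n_circuits + n_extra_de_mirna > n_mirna ||
        n_circuits + n_extra_de_mrna > n_mrna)
      stop("planted DE features exceed class size", call. = FALSE)
    if (len_circ < seed_len + 60 || len_mrna < seed_len + 60)
      stop("target sequences too short to host planted sites", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' Plant a seed-complementary binding site in a target sequence
#'
#' Replaces `seed_len` bases of the target, starting at 0-based `position`,
#' with the reverse complement of miRNA positions 2..(1+seed_len) (1-based on
#' the miRNA, written 5'->3' on the target). With `seed_len = 0` the target is
#' returned unchanged.
#'
#' @param target_seq Canonical RNA target sequence.
#' @param mirna_seq Canonical RNA miRNA sequence, length >= 1 + seed_len.
#' @param position 0-based start of the planted site on the target.
#' @param seed_len Number of miRNA positions (from position 2) to complement.
#' @return The modified target sequence.
#' @examples
#' plant_site("AAAAAAAAAA", "UGGAAUGUAA", 0, 7) # starts with "ACAUUCC"
#' @export
plant_site <- function(target_seq, mirna_seq, position, seed_len) {
  if (seed_len == 0) return(target_seq)
  n <- nchar(target_seq)
  if (position < 0 || position + seed_len > n)
    stop(sprintf("site [%d, %d) out of range for target of length %d",
                 position, position + seed_len, n), call. = FALSE)
  if (nchar(mirna_seq) < 1 + seed_len)
    stop("miRNA shorter than 1 + seed_len", call. = FALSE)
  site <- revcomp_rna(substr(mirna_seq, 2, 1 + seed_len))
  paste0(substr(target_seq, 1, position), site,
         substr(target_seq, position + seed_len + 1, n))
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Base placed 3' of a planted site (opposite miRNA position 1): it must not
# Watson-Crick- or wobble-pair with position 1 (so the local alignment never
# extends past position 2 and recovery is coordinate-exact) and must not be
# an A (which would add a 7mer-A1/8mer anchor and shift the site call).
nonpairing_base <- function(base) {
  excluded <- c("A", chartr("ACGU", "UGCA", base),
                switch(base, G = "U", U = "G", character(0)))
  setdiff(c("C", "G", "U"), excluded)[1L]
}

#' Simulate a self-consistent OVX-like ceRNA study
#'
#' Generates count matrices (circRNA, mRNA), a miRNA log2-intensity matrix,
#' mature-miRNA and target FASTA-style sequence sets, an annotation gene-set
#' collection, and a ground-truth table of planted DE features, circuits and
#' binding sites. Identical `config` (including its `seed`) gives bit-identical
#' output.
#'
#' Planted circuit structure: circuit i uses the i-th circRNA, miRNA and mRNA.
#' Circuit directions alternate (circRNA/mRNA up + miRNA down in case, then the
#' mirror). Each circuit's circRNA and mRNA sequence carries one exact
#' reverse-complement site of the circuit miRNA (recorded in
#' `truth$planted_sites`, 0-based half-open coordinates), and a shared
#' per-sample latent sponge factor induces the ceRNA correlation signs
#' (circ-mRNA positive, miRNA-circ and miRNA-mRNA negative).
#'
#' @param config A [simulation_config()].
#' @return List with elements `circ`, `mrna` (counts `expr_matrix`), `mirna`
#'   (log-intensity `expr_matrix`), `mirna_fa`, `target_fa` (`rna_seqs`;
#'   `target_fa` holds the mRNA targets followed by the circRNA pseudo-
#'   sequences, with a per-record `target_class` attribute), `annotation`
#'   (`gene_sets`) and `truth` (list `de_features`, `circuits`,
#'   `planted_sites`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_samp <- config$n_case + config$n_control
  samples <- c(sprintf("OVX_%d", seq_len(config$n_case)),
               sprintf("Sham_%d", seq_len(config$n_control)))
  design <- structure(rep(c("case", "control"),
                          c(config$n_case, config$n_control)), names = samples)
  g <- ifelse(design == "case", 0.5, -0.5)

  circ_ids <- sprintf("circRNA_%04d", seq_len(config$n_circ))
  mirna_ids <- sprintf("mmu-miR-sim-%03d", seq_len(config$n_mirna))
  mrna_ids <- sprintf("Gene%04d", seq_len(config$n_mrna))

  nc <- config$n_circuits
  dir_circuit <- if (nc) rep_len(c(1, -1), nc) else numeric(0)
  plan_de <- function(ids, n_extra, circuit_dirs) {
    lfc <- numeric(length(ids))
    lfc[seq_along(circuit_dirs)] <- circuit_dirs * config$lfc_de
    if (n_extra > 0) {
      idx <- length(circuit_dirs) + seq_len(n_extra)
      lfc[idx] <- rep_len(c(1, -1), n_extra) * config$lfc_de
    }
    lfc
  }
  lfc_circ <- plan_de(circ_ids, config$n_extra_de_circ, dir_circuit)
  lfc_mrna <- plan_de(mrna_ids, config$n_extra_de_mrna, dir_circuit)
  lfc_mirna <- plan_de(mirna_ids, config$n_extra_de_mirna, -dir_circuit)

  sf <- exp(runif(n_samp, log(config$sf_range[1]), log(config$sf_range[2])))
  z <- if (nc) matrix(rnorm(nc * n_samp), nc, n_samp) else
    matrix(0, 0, n_samp)

  # Shared/residual decomposition of the biological variance of circuit
  # members: shared log-normal factor variance rho*log(1+alpha), residual NB
  # dispersion (1+alpha)^(1-rho)-1, so the marginal dispersion stays ~alpha.
  alpha <- config$nb_dispersion
  rho <- config$sponge_rho
  ssh <- if (alpha > 0) sqrt(rho * log1p(alpha)) else 0
  alpha_resid <- if (alpha > 0) (1 + alpha)^(1 - rho) - 1 else 0

  sim_counts <- function(ids, lfc) {
    n_feat <- length(ids)
    base <- exp(rnorm(n_feat, config$base_mean_log, config$base_mean_sd))
    mu <- outer(base, sf) * 2^(outer(lfc, g))
    disp <- rep(alpha, n_feat)
    if (nc) {
      idx <- seq_len(nc)
      mu[idx, ] <- mu[idx, ] * exp(ssh * z - ssh^2 / 2)
      disp[idx] <- alpha_resid
    }
    x <- matrix(0, n_feat, n_samp, dimnames = list(ids, samples))
    for (f in seq_len(n_feat)) {
      x[f, ] <- if (disp[f] > 1e-12)
        rnbinom(n_samp, mu = mu[f, ], size = 1 / disp[f])
      else
        stats::rpois(n_samp, mu[f, ])
    }
    expression_matrix(x, "counts", design)
  }
  circ <- sim_counts(circ_ids, lfc_circ)
  mrna <- sim_counts(mrna_ids, lfc_mrna)

  ibase <- rnorm(config$n_mirna, config$intensity_base, config$intensity_base_sd)
  y <- outer(ibase, rep(1, n_samp)) + outer(lfc_mirna, g) +
    matrix(rnorm(config$n_mirna * n_samp, 0,
                 config$intensity_sd * sqrt(ifelse(seq_len(config$n_mirna) <= nc,
                                                   1 - rho, 1))),
           config$n_mirna, n_samp)
  if (nc) {
    idx <- seq_len(nc)
    y[idx, ] <- y[idx, ] - sqrt(rho) * config$intensity_sd * z
  }
  dimnames(y) <- list(mirna_ids, samples)
  mirna <- expression_matrix(y, "log_intensity", design)

  mirna_seqs <- random_rna(config$n_mirna, config$mirna_len)
  names(mirna_seqs) <- mirna_ids
  mrna_seqs <- random_rna(config$n_mrna, config$len_mrna)
  names(mrna_seqs) <- mrna_ids
  circ_seqs <- random_rna(config$n_circ, config$len_circ)
  names(circ_seqs) <- circ_ids

  sites <- list()
  plant_into <- function(seqs, target_id, mirna_idx, len) {
    pos <- sample.int(len - config$seed_len - 42L, 1L) + 39L  # 0-based start
    s <- plant_site(seqs[[target_id]], mirna_seqs[[mirna_idx]], pos,
                    config$seed_len)
    # pin the base opposite miRNA position 1 to a non-pairing base
    adj <- pos + config$seed_len + 1L  # 1-based index of the 3'-adjacent base
    m1 <- substr(mirna_seqs[[mirna_idx]], 1, 1)
    substr(s, adj, adj) <- nonpairing_base(m1)
    seqs[[target_id]] <- s
    list(seqs = seqs,
         site = data.frame(target_id = target_id, start = as.integer(pos),
                           end = as.integer(pos + config$seed_len),
                           mirna_id = mirna_ids[mirna_idx],
                           stringsAsFactors = FALSE))
  }
  if (nc) {
    for (i in seq_len(nc)) {
      pm <- plant_into(mrna_seqs, mrna_ids[i], i, config$len_mrna)
      mrna_seqs <- pm$seqs
      pc <- plant_into(circ_seqs, circ_ids[i], i, config$len_circ)
      circ_seqs <- pc$seqs
      sites <- c(sites, list(pm$site, pc$site))
    }
  }
  planted_sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(target_id = character(0), start = integer(0), end = integer(0),
               mirna_id = character(0), stringsAsFactors = FALSE)

  target_fa <- rna_seqs(c(mrna_seqs, circ_seqs), "mRNA_target")
  attr(target_fa, "target_class") <-
    structure(rep(c("mRNA", "circRNA"), c(config$n_mrna, config$n_circ)),
              names = c(mrna_ids, circ_ids))
  mirna_fa <- rna_seqs(mirna_seqs, "miRNA")

  sets <- vector("list", config$n_sets)
  names(sets) <- sprintf("term_%02d", seq_len(config$n_sets))
  first_size <- min(max(20L, nc + 5L), config$n_mrna)
  sets[[1L]] <- unique(c(mrna_ids[seq_len(nc)],
                         sample(mrna_ids, first_size - nc)))
  for (k in seq_len(config$n_sets)[-1L])
    sets[[k]] <- sample(mrna_ids, min(sample(10:40, 1), config$n_mrna))
  annotation <- gene_set_collection(
    sets,
    descriptions = structure(sprintf("synthetic pathway %02d",
                                     seq_len(config$n_sets)),
                             names = names(sets)),
    universe = mrna_ids)

  de_features <- rbind(
    data.frame(feature_id = circ_ids, class = "circRNA", lfc = lfc_circ,
               stringsAsFactors = FALSE),
    data.frame(feature_id = mirna_ids, class = "miRNA", lfc = lfc_mirna,
               stringsAsFactors = FALSE),
    data.frame(feature_id = mrna_ids, class = "mRNA", lfc = lfc_mrna,
               stringsAsFactors = FALSE))
  de_features <- de_features[de_features$lfc != 0, , drop = FALSE]
  de_features$direction <- ifelse(de_features$lfc > 0, "up", "down")
  rownames(de_features) <- NULL

  circuits <- data.frame(circ_id = circ_ids[seq_len(nc)],
                         mirna_id = mirna_ids[seq_len(nc)],
                         mrna_id = mrna_ids[seq_len(nc)],
                         direction = ifelse(dir_circuit > 0, "up", "down"),
                         stringsAsFactors = FALSE)

  list(circ = circ, mrna = mrna, mirna = mirna,
       mirna_fa = mirna_fa, target_fa = target_fa, annotation = annotation,
       truth = list(de_features = de_features, circuits = circuits,
                    planted_sites = planted_sites),
       config = config)
}
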