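#' Simulate a platelet-like spliced count cohort
#'
#' Generates negative-binomial counts (variance mu + phi * mu^2) over a
#' log-normal baseline of gene means, emulating the statistical structure of
#' intron-spanning platelet RNA-seq profiles: a two-group fold-change effect
#' on a subset of genes, log-normal library-size variation, a planted set of
#' stable genes (high-abundance, near-Poisson genes whose counts track
#' library size and are age-independent -- the negative-control truth for
#' RUV), an additive-on-log-scale latent batch factor on a gene subset, and
#' an age-coupled gene subset. All memberships are returned in a truth
#' record sufficient to score any downstream stage. Pure function of
#' (parameters, seed).
#'
#' @param n_genes,n_samples cohort dimensions (defaults 4500 genes, the
#'   scale of the spliced platelet repertoire, and 100 samples).
#' @param frac_de fraction of genes differentially spliced between groups.
#' @param logfc absolute log2 fold change of the planted effect (sign
#'   random per gene).
#' @param dispersion NB dispersion phi of regular genes.
#' @param n_stable number of planted stable genes.
#' @param batch latent batch factor spec: list with \code{sd} (log-scale
#'   loading) and either \code{frac} (fraction of genes, default 0.05) or
#'   \code{n_genes}; NULL disables.
#' @param age_effect age coupling spec: list with \code{beta} (log-scale
#'   slope per year) and either \code{frac} (default 0.02) or
#'   \code{n_genes}; NULL disables.
#' @param lib_sd log-normal sd of the per-sample size factors.
#' @param base_mean median baseline gene mean.
#' @param roles named integer vector of cohort-role sizes
#'   (training/evaluation/validation), stratified by group; remaining
#'   samples get role "unassigned".
#' @param seed RNG seed.
#' @return list with \code{data} (a \linkS4class{SplicedCounts}) and
#'   \code{truth}.
#' @export
simulateCounts <- function(n_genes = 4500, n_samples = 100, frac_de = 0.1,
                           logfc = 1, dispersion = 0.2, n_stable = 200,
                           batch = list(frac = 0.05, sd = 0.5),
                           age_effect = list(frac = 0.02, beta = 0.02),
                           lib_sd = 0.3, base_mean = 30,
                           roles = NULL, seed = 1) {
  stopifnot(frac_de >= 0, frac_de <= 1, n_genes > 0, n_samples >= 4)
  set.seed(seed)
  genes <- sprintf("ENSG%08d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))
  group <- factor(rep_len(c("nonCancer", "NSCLC"), n_samples),
                  levels = c("nonCancer", "NSCLC"))
  age <- round(stats::runif(n_samples, 30, 80))

  role <- rep("unassigned", n_samples)
  if (!is.null(roles)) {
    for (lv in levels(group)) {
      idx <- which(group == lv)
      pos <- 1L
      for (rn in names(roles)) {
        take <- min(ceiling(roles[[rn]] / nlevels(group)),
                    length(idx) - pos + 1L)
        if (take > 0) {
          role[idx[pos:(pos + take - 1L)]] <- rn
          pos <- pos + take
        }
      }
    }
  }

  # Library size is a technical factor, independent of demographics by
  # assumption, and the emulated study age-matches its cohorts; the realized
  # log size factors are therefore decorrelated from age within each cohort
  # stratum, so planted stable genes (libsize-tracking, age-independent)
  # actually carry that property in every cohort.
  lsf <- stats::rnorm(n_samples, 0, lib_sd)
  for (rn in unique(role)) {
    idx <- role == rn
    if (sum(idx) >= 4 && stats::sd(age[idx]) > 0)
      lsf[idx] <- stats::residuals(stats::lm(lsf[idx] ~ age[idx]))
  }
  if (stats::sd(lsf) > 0) lsf <- lsf * lib_sd / stats::sd(lsf)
  size_factor <- exp(lsf)

  mu0 <- stats::rlnorm(n_genes, log(base_mean), 1.2)
  phi <- rep(dispersion, n_genes)
  names(mu0) <- names(phi) <- genes

  stable_genes <- character(0)
  if (n_stable > 0) {
    stable_genes <- sample(genes, n_stable)
    mu0[stable_genes] <- stats::rlnorm(n_stable, log(300), 0.3)
    phi[stable_genes] <- 0.005
  }
  pool <- setdiff(genes, stable_genes)
  n_de <- round(frac_de * n_genes)
  de_genes <- if (n_de > 0) sample(pool, min(n_de, length(pool)))
              else character(0)
  de_sign <- stats::setNames(sample(c(-1, 1), length(de_genes),
                                    replace = TRUE), de_genes)
  pool <- setdiff(pool, de_genes)
  n_from_spec <- function(spec)
    if (!is.null(spec$n_genes)) spec$n_genes else round(spec$frac * n_genes)
  batch_genes <- character(0); batch_factor <- rep(0, n_samples)
  if (!is.null(batch) && n_from_spec(batch) > 0) {
    batch_genes <- sample(pool, min(n_from_spec(batch), length(pool)))
    batch_factor <- stats::rnorm(n_samples)
    pool <- setdiff(pool, batch_genes)
  }
  age_genes <- character(0)
  if (!is.null(age_effect) && n_from_spec(age_effect) > 0)
    age_genes <- sample(pool, min(n_from_spec(age_effect), length(pool)))

  logmu <- matrix(log(mu0), n_genes, n_samples,
                  dimnames = list(genes, samples))
  if (length(de_genes))
    logmu[de_genes, group == "NSCLC"] <-
      logmu[de_genes, group == "NSCLC"] + de_sign * logfc * log(2)
  if (length(batch_genes))
    logmu[batch_genes, ] <- logmu[batch_genes, ] +
      rep(batch$sd * batch_factor, each = length(batch_genes))
  if (length(age_genes))
    logmu[age_genes, ] <- logmu[age_genes, ] +
      rep(age_effect$beta * (age - mean(age)), each = length(age_genes))
  mu <- exp(logmu) * rep(size_factor, each = n_genes)

  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu,
                                  size = rep(1 / pmax(phi, 1e-8), n_samples)),
                   n_genes, n_samples, dimnames = list(genes, samples))

  ann <- data.frame(sample_id = samples, group = as.character(group),
                    age = age,
                    storage = sample(c("<12h", ">12h"), n_samples, TRUE),
                    gender = sample(c("F", "M"), n_samples, TRUE),
                    smoking = sample(c("current", "former", "never"),
                                     n_samples, TRUE),
                    cohort_role = role, site = "simulated",
                    stringsAsFactors = FALSE)
  list(data = SplicedCounts(counts, ann),
       truth = list(de_genes = de_genes, de_sign = de_sign,
                    stable_genes = stable_genes, batch_genes = batch_genes,
                    batch_factor = stats::setNames(batch_factor, samples),
                    age_genes = age_genes,
                    size_factors = stats::setNames(size_factor, samples),
                    seed = seed))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Background block guaranteed free of any of `avoid` (exact A/C/G/T strings).
.clean_block <- function(n, avoid, max_try = 100) {
  for (i in seq_len(max_try)) {
    s <- .random_dna(n)
    if (sum(vapply(avoid, function(m)
      countMotifHits(s, m), integer(1))) == 0L) return(s)
  }
  stop("could not generate a motif-free background block")
}

#' Simulate a UTR fixture with a planted RBP signal
#'
#' Writes a toy genome FASTA (one chromosome per gene), an Ensembl-dialect
#' GTF (gene/transcript/exon/CDS/UTR features), a UTR read-coverage TSV and
#' a per-gene logFC table. For the planted RBP, the number of motif
#' instances inserted into each gene's 3' UTR is proportional to that gene's
#' logFC plus noise; the assembled UTR is verified to contain exactly the
#' inserted number of hits (background regenerated otherwise), so the
#' generator/scanner round trip is exact. A fraction of 3' UTRs is assigned
#' coverage below the 5-read threshold to exercise the coverage gate.
#'
#' @param n_genes number of genes.
#' @param motif_sets list of RBP records (\code{\link{parseMotifTable}}
#'   shape).
#' @param planted_rbp id of the RBP whose sites track logFC.
#' @param effect slope of inserted-site count on logFC (0 = null).
#' @param low_frac fraction of 3' UTRs given sub-threshold coverage.
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return list with file paths (\code{genome}, \code{gtf},
#'   \code{coverage}, \code{logfc}) and \code{truth} (inserted counts,
#'   logFC, planted RBP).
#' @export
simulateUTRFixture <- function(n_genes = 100, motif_sets, planted_rbp,
                               effect = 1, low_frac = 0.1,
                               dir = tempfile("utrfix"), seed = 1) {
  stopifnot(planted_rbp %in% vapply(motif_sets, `[[`, "", "rbp_id"))
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  planted <- motif_sets[[which(vapply(motif_sets, `[[`, "", "rbp_id") ==
                                 planted_rbp)]]$expanded
  logfc <- stats::rnorm(n_genes)
  k <- pmax(0L, round(2 + effect * logfc + stats::rnorm(n_genes, 0, 0.5)))
  genes <- sprintf("G%04d", seq_len(n_genes))
  seqs <- character(n_genes)
  gtf_rows <- list()
  cov_rows <- list()
  for (i in seq_len(n_genes)) {
    utr5 <- .random_dna(60)
    cds <- paste0("ATG", .random_dna(27))
    # 3' UTR: clean blocks interleaved with exactly k[i] motif instances
    repeat {
      blocks <- replicate(k[i] + 1L, .clean_block(30, planted))
      ins <- if (k[i] > 0) sample(planted, k[i], replace = TRUE)
             else character(0)
      utr3 <- blocks[1L]
      for (j in seq_len(k[i]))
        utr3 <- paste0(utr3, ins[j], blocks[j + 1L])
      if (countMotifHits(utr3, planted) == k[i]) break
    }
    seqs[i] <- paste0(utr5, cds, utr3)
    chr <- paste0("chr_", genes[i])
    tx <- paste0(genes[i], ".t1")
    at <- function(type, s, e) sprintf(
      "%s\tsim\t%s\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      chr, type, s, e, genes[i], tx)
    l5 <- nchar(utr5); lc <- nchar(cds); l3 <- nchar(utr3)
    gtf_rows[[i]] <- c(
      at("gene", 1L, l5 + lc + l3),
      at("transcript", 1L, l5 + lc + l3),
      at("exon", 1L, l5 + lc + l3),
      at("five_prime_utr", 1L, l5),
      at("CDS", l5 + 1L, l5 + lc),
      at("three_prime_utr", l5 + lc + 1L, l5 + lc + l3))
    low3 <- stats::runif(1) < low_frac
    cov_rows[[i]] <- data.frame(
      transcript_id = tx, side = c("five_prime", "three_prime"),
      read_count = c(sample(3:50, 1L),
                     if (low3) sample(0:4, 1L) else sample(5:100, 1L)),
      stringsAsFactors = FALSE)
  }
  genome_path <- file.path(dir, "genome.fa")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- paste0("chr_", genes)
  Biostrings::writeXStringSet(ss, genome_path)
  gtf_path <- file.path(dir, "annotation.gtf")
  writeLines(unlist(gtf_rows), gtf_path)
  cov_path <- file.path(dir, "coverage.tsv")
  utils::write.table(do.call(rbind, cov_rows), cov_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logfc_path <- file.path(dir, "logfc.tsv")
  utils::write.table(data.frame(gene_id = genes, logFC = logfc),
                     logfc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(genome = genome_path, gtf = gtf_path, coverage = cov_path,
       logfc = logfc_path,
       truth = list(inserted = stats::setNames(k, genes),
                    logfc = stats::setNames(logfc, genes),
                    planted_rbp = planted_rbp, seed = seed))
}

#' Simulate a percent-spliced-in fixture
#'
#' Beta-distributed PSI values per event with a planted group-2 mean shift
#' on a subset of events (shifted events draw their baseline with headroom
#' so the planted shift is realized unclipped); inclusion/exclusion assigned
#' counts are binomial given PSI and a Poisson total-read draw.
#'
#' @param n_events,n_samples dimensions (half of samples per group).
#' @param frac_shifted fraction of events shifted in group 2.
#' @param delta PSI mean shift in [-1, 1].
#' @param concentration beta concentration (a + b).
#' @param mean_reads mean assigned reads per event and sample.
#' @param seed RNG seed.
#' @return list with \code{psi}, \code{inc}, \code{exc} matrices,
#'   \code{group} and \code{truth} (shifted events, planted delta).
#' @export
simulatePSIFixture <- function(n_events = 200, n_samples = 100,
                               frac_shifted = 0.2, delta = 0.3,
                               concentration = 30, mean_reads = 50,
                               seed = 1) {
  stopifnot(delta >= -1, delta <= 1)
  set.seed(seed)
  events <- sprintf("E%04d", seq_len(n_events))
  samples <- sprintf("S%03d", seq_len(n_samples))
  group <- factor(rep_len(c("nonCancer", "NSCLC"), n_samples),
                  levels = c("nonCancer", "NSCLC"))
  n_shift <- round(frac_shifted * n_events)
  shifted <- if (n_shift > 0) sample(events, n_shift) else character(0)
  base <- stats::runif(n_events, 0.2, 0.8)
  names(base) <- events
  if (length(shifted)) {
    lo <- max(0.05, 0.05 - min(0, delta))
    hi <- min(0.95, 0.95 - max(0, delta))
    base[shifted] <- stats::runif(length(shifted), lo, hi)
  }
  m <- matrix(base, n_events, n_samples, dimnames = list(events, samples))
  if (length(shifted))
    m[shifted, group == "NSCLC"] <-
      pmin(0.98, pmax(0.02, m[shifted, group == "NSCLC"] + delta))
  psi <- matrix(stats::rbeta(n_events * n_samples, m * concentration,
                             (1 - m) * concentration),
                n_events, n_samples, dimnames = list(events, samples))
  total <- matrix(stats::rpois(n_events * n_samples, mean_reads),
                  n_events, n_samples, dimnames = list(events, samples))
  inc <- matrix(stats::rbinom(n_events * n_samples, total, psi),
                n_events, n_samples, dimnames = list(events, samples))
  exc <- total - inc
  list(psi = psi, inc = inc, exc = exc,
       group = stats::setNames(as.character(group), samples),
       truth = list(shifted = shifted, delta = delta, base = base,
                    seed = seed))
}
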