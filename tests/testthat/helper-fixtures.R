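# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Small SplicedCounts with optional annotation columns.
toy_counts <- function(m, group = NULL, age = NULL, role = NULL) {
  ann <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  if (!is.null(group)) ann$group <- group
  if (!is.null(age)) ann$age <- age
  if (!is.null(role)) ann$cohort_role <- role
  SplicedCounts(m, ann)
}

rand_counts <- function(n_genes, n_samples, lambda = 50, seed = 1,
                        prefix = "g") {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(paste0(prefix, seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m
}

# Independent brute-force TMM oracle following the trimmed weighted mean of
# M-values definition: M and A over genes nonzero in both columns, doubly
# trimmed (30% by M, 5% by A, rank-based), inverse-asymptotic-variance
# weights. Returns the raw pairwise factor of y against ref.
oracle_tmm <- function(y, ref) {
  Ny <- sum(y); Nr <- sum(ref)
  keep <- y > 0 & ref > 0
  y <- y[keep]; ref <- ref[keep]
  M <- log2((y / Ny) / (ref / Nr))
  A <- (log2(y / Ny) + log2(ref / Nr)) / 2
  v <- (Ny - y) / (Ny * y) + (Nr - ref) / (Nr * ref)
  n <- length(M)
  loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  kp <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[kp] / v[kp]) / sum(1 / v[kp]))
}

# All-pairs AUC oracle (ties counted 1/2).
oracle_auc <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Double-loop Benjamini-Hochberg oracle.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, min(1, p[ord[j]] * n / j))
    adj[ord[i]] <- best
  }
  adj
}

# Plain NB log-likelihood for the GLM oracle.
nb_ll <- function(y, mu, phi) sum(dnbinom(y, size = 1 / phi, mu = mu,
                                          log = TRUE))

default_theta <- c(libsize_threshold = 0.8, fdr_threshold = 0.05,
                   corr_cutoff = 0.9, rfe_size = 20)

# Coarse grid keeps SVM tuning fast in tests; resolution is a runtime knob,
# not a modeling choice.
fast_train <- function(x, tr, theta = default_theta, seed = 3, ...) {
  trainClassifier(x, tr, theta = theta,
                  gamma_exp = seq(-20, 0, 4), cost_exp = seq(0, 20, 4),
                  refine_particles = 5, refine_iter = 5, seed = seed, ...)
}

# A well-separated simulated cohort shared by classifier tests.
separable_cohort <- function(seed = 11) {
  simulateCounts(n_genes = 400, n_samples = 80, frac_de = 0.15, logfc = 2,
                 n_stable = 50,
                 roles = c(training = 40, evaluation = 16, validation = 24),
                 seed = seed)
}

# Tiny synthetic RBP motif table written as TSV; returns the path.
write_motif_table <- function(path, extra_species = TRUE) {
  tab <- data.frame(
    species = c("Homo_sapiens", "Homo_sapiens", "Homo_sapiens",
                "Homo_sapiens", if (extra_species) "Mus_musculus"),
    rbp_id = c("RBP1", "RBP1", "RBP2", "RBP3",
               if (extra_species) "RBPX"),
    motif = c("ACGUA", "ACGTA", "UGCWG", "RYGCA",
              if (extra_species) "AAAA"),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
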