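# shared fixture constructors (all fixtures are built in code)

# genotype matrix from a plain matrix, loci named L1..Lk on one linkage group
make_gm <- function(d, lg = "LG01", pos = seq_len(ncol(d)), ids = NULL) {
  d <- as.matrix(d)
  genotype_matrix(d, locus_table(paste0("L", seq_len(ncol(d))), lg, pos), ids)
}

# allele-count table straight from numbers (one population)
make_counts <- function(n_alt, n_total, n_het, n_ind,
                        ids = paste0("L", seq_along(n_alt))) {
  out <- data.frame(locus_id = ids, n_alt = as.integer(n_alt),
                    n_total = as.integer(n_total), n_het = as.integer(n_het),
                    n_ind = as.integer(n_ind), stringsAsFactors = FALSE)
  class(out) <- c("allele_counts", "data.frame")
  out
}

# random dosage matrix with missingness, reproducible
random_gm <- function(n, L, miss = 0.05, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    p <- runif(L, 0.1, 0.9)
    d <- matrix(rbinom(n * L, 2, rep(p, each = n)), nrow = n)
    d[matrix(runif(n * L) < miss, n, L)] <- NA_integer_
    make_gm(d)
  })
}
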