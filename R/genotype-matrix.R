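#' Build a locus information table
#'
#' A locus table records, for each biallelic SNP, its identifier, the linkage
#' group it maps to, its position on the linkage map in centimorgans, and the
#' ref/alt allele labels. It is carried alongside every genotype matrix and
#' consumed by the map-based panel selection.
#'
#' @param locus_id Character vector of unique locus identifiers.
#' @param linkage_group Character vector of linkage-group labels (recycled).
#' @param map_pos Numeric vector of map positions in centimorgans
#'   (non-negative; `NA` allowed for unmapped loci).
#' @param ref,alt Allele labels (recycled); purely descriptive, dosage is
#'   always the count of `alt` alleles.
#' @return A `data.frame` with columns `locus_id`, `linkage_group`,
#'   `map_pos`, `ref`, `alt`.
#' @export
locus_table <- function(locus_id, linkage_group = NA_character_,
                        map_pos = NA_real_, ref = "A", alt = "B") {
  locus_id <- as.character(locus_id)
  if (anyDuplicated(locus_id)) {
    stop("duplicated locus_id: ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "))
  }
  n <- length(locus_id)
  map_pos <- as.numeric(map_pos)
  if (any(is.infinite(map_pos))) stop("map_pos must be finite or NA")
  if (any(map_pos < 0, na.rm = TRUE)) stop("map_pos must be non-negative")
  data.frame(locus_id = locus_id,
             linkage_group = rep_len(as.character(linkage_group), n),
             map_pos = rep_len(map_pos, n),
             ref = rep_len(as.character(ref), n),
             alt = rep_len(as.character(alt), n),
             stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' The central data container: diploid biallelic genotypes stored as alt-allele
#' dosages in `{0, 1, 2, NA}` for a set of individuals at a set of loci, with
#' an attached locus table.
#'
#' @param dosage Integer (or coercible) matrix, individuals in rows and loci in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param loci Either a locus table (see [locus_table()]) with one row per
#'   column of `dosage`, or a character vector of locus ids.
#' @param individuals Character vector of individual ids; defaults to the
#'   rownames of `dosage` or `ind1..indN`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (named integer matrix) and `loci` (locus table).
#' @export
genotype_matrix <- function(dosage, loci, individuals = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) < 1L || ncol(dosage) < 1L) {
    stop("genotype matrix needs at least 1 individual and 1 locus")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (is.character(loci)) loci <- locus_table(loci)
  stopifnot(is.data.frame(loci), all(c("locus_id", "linkage_group",
                                       "map_pos") %in% names(loci)))
  if (nrow(loci) != ncol(dosage)) {
    stop("locus table has ", nrow(loci), " rows but dosage has ",
         ncol(dosage), " columns")
  }
  if (anyDuplicated(loci$locus_id)) stop("duplicated locus ids")
  if (is.null(individuals)) {
    individuals <- rownames(dosage)
    if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(dosage)))
  }
  individuals <- as.character(individuals)
  if (length(individuals) != nrow(dosage)) {
    stop("individuals length does not match dosage rows")
  }
  if (anyDuplicated(individuals)) stop("duplicated individual ids")
  dimnames(dosage) <- list(individuals, loci$locus_id)
  structure(list(dosage = dosage, loci = loci), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " loci; ",
      format(100 * mean(is.na(x$dosage)), digits = 3),
      "% missing\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param individuals,loci Character ids (or integer/logical indices) to keep;
#'   `NULL` keeps all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ii <- if (is.null(individuals)) seq_len(nrow(x$dosage)) else individuals
  if (is.character(ii)) {
    miss <- setdiff(ii, rownames(x$dosage))
    if (length(miss)) stop("unknown individuals: ", paste(miss, collapse = ", "))
  }
  jj <- if (is.null(loci)) seq_len(ncol(x$dosage)) else loci
  if (is.character(jj)) {
    miss <- setdiff(jj, x$loci$locus_id)
    if (length(miss)) stop("unknown loci: ", paste(miss, collapse = ", "))
    jj <- match(jj, x$loci$locus_id)
  }
  d <- x$dosage[ii, jj, drop = FALSE]
  genotype_matrix(d, x$loci[jj, , drop = FALSE], rownames(d))
}

#' Stack two genotype matrices over the same loci
#'
#' @param a,b `genotype_matrix` objects sharing an identical locus list.
#' @return A `genotype_matrix` containing the individuals of both.
#' @export
rbind_genotypes <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  if (!identical(a$loci$locus_id, b$loci$locus_id)) {
    stop("locus lists differ")
  }
  genotype_matrix(rbind(a$dosage, b$dosage), a$loci,
                  c(rownames(a$dosage), rownames(b$dosage)))
}

# internal: deterministic seeding helper. All generator randomness flows from
# one user seed; independent stages draw from named substreams so that adding
# draws to one stage never perturbs another.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
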