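#' Read genotypes from a Genepop file
#'
#' Parses the classic Genepop format with 4-digit two-allele codes
#' (e.g. `0102` = heterozygote for alleles `01` and `02`; `0000` = missing).
#' Allele codes at each locus are oriented numerically: the smallest observed
#' code is the ref allele, the largest the alt allele, so dosage orientation
#' is stable across files sharing a locus list. Populations separated by
#' `Pop` lines are recorded in the `pop` attribute.
#'
#' @param path File path.
#' @return A [genotype_matrix()] with attribute `pop` (character vector of
#'   population indices `pop1, pop2, ...` per individual) and attribute
#'   `allele_codes` (per-locus ref/alt code table).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("not a Genepop file: too short")
  lines <- lines[!grepl("^\\s*$", lines)]
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(pop_idx) == 0L) stop("no 'Pop' line found")
  header <- lines[2:(pop_idx[1] - 1)]
  loci <- unlist(strsplit(paste(header, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[loci != ""]
  if (anyDuplicated(loci)) {
    stop("duplicated locus names: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  }
  ids <- character(0)
  pops <- character(0)
  geno <- list()
  pop_no <- 0L
  for (k in seq(pop_idx[1], length(lines))) {
    line <- lines[k]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop_no <- pop_no + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L) stop("malformed record at line ", k)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci)) {
      stop("line ", k, ": expected ", length(loci), " genotypes, got ",
           length(codes))
    }
    if (any(!grepl("^[0-9]{4}$", codes))) {
      stop("line ", k, ": invalid genotype code(s): ",
           paste(codes[!grepl("^[0-9]{4}$", codes)], collapse = " "))
    }
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop", pop_no))
    geno[[length(geno) + 1L]] <- codes
  }
  gmat <- do.call(rbind, geno)
  a1 <- substr(gmat, 1, 2)
  a2 <- substr(gmat, 3, 4)
  dosage <- matrix(NA_integer_, nrow(gmat), ncol(gmat))
  codes_tab <- data.frame(locus_id = loci, ref = NA_character_,
                          alt = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    obs <- c(a1[, j], a2[, j])
    obs <- sort(unique(obs[obs != "00"]))
    if (length(obs) > 2L) {
      stop("locus ", loci[j], ": more than two alleles (",
           paste(obs, collapse = ","), ")")
    }
    if (length(obs) == 0L) obs <- c("01", "02")
    if (length(obs) == 1L) obs <- c(obs, NA_character_)
    ref <- obs[1]; alt <- obs[2]
    codes_tab$ref[j] <- ref; codes_tab$alt[j] <- alt
    miss <- a1[, j] == "00" | a2[, j] == "00"
    dj <- (!is.na(alt) & a1[, j] == alt) + (!is.na(alt) & a2[, j] == alt)
    dj[miss] <- NA_integer_
    dosage[, j] <- dj
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  gm <- genotype_matrix(dosage,
                        locus_table(loci, ref = codes_tab$ref,
                                    alt = ifelse(is.na(codes_tab$alt), "??",
                                                 codes_tab$alt)),
                        ids)
  attr(gm, "pop") <- pops
  attr(gm, "allele_codes") <- codes_tab
  gm
}

#' Write genotypes to a Genepop file
#'
#' Writes dosages back to 4-digit codes using ref = `01`, alt = `02`
#' (or the allele-code attribute of a matrix read by [read_genepop()]).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param pop Optional character vector grouping individuals into populations
#'   (runs of equal values become `Pop` blocks); defaults to one population.
#' @param title Header line.
#' @export
write_genepop <- function(gm, path, pop = NULL, title = "gsimix export") {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(pop)) pop <- attr(gm, "pop")
  if (is.null(pop)) pop <- rep("pop1", nrow(gm$dosage))
  code <- c("0101", "0102", "0202")
  lines <- c(title, gm$loci$locus_id)
  for (p in unique(pop)) {
    lines <- c(lines, "Pop")
    for (i in which(pop == p)) {
      g <- gm$dosage[i, ]
      s <- ifelse(is.na(g), "0000", code[g + 1L])
      lines <- c(lines, paste0(rownames(gm$dosage)[i], " ,  ",
                               paste(s, collapse = " ")))
    }
  }
  writeLines(lines, path)
}

#' Read/write wide dosage CSV
#'
#' Wide format: first column `individual_id`, one column per locus, cells
#' 0/1/2 or empty (`NA`).
#'
#' @param path File path.
#' @param map Optional locus table to attach (matched by locus id).
#' @return A [genotype_matrix()].
#' @export
read_dosage_csv <- function(path, map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  d <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(d) <- "integer"
  loci <- colnames(d)
  lt <- if (is.null(map)) locus_table(loci) else {
    idx <- match(loci, map$locus_id)
    if (anyNA(idx)) stop("loci absent from map: ",
                         paste(loci[is.na(idx)], collapse = ", "))
    map[idx, , drop = FALSE]
  }
  genotype_matrix(d, lt, ids)
}

#' @rdname read_dosage_csv
#' @param gm A [genotype_matrix()] to write.
#' @export
write_dosage_csv <- function(gm, path) {
  df <- data.frame(individual_id = rownames(gm$dosage),
                   gm$dosage, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("individual_id", gm$loci$locus_id)
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Read/write a locus map CSV
#'
#' Columns `locus_id`, `linkage_group`, `cM`.
#'
#' @param path File path.
#' @return A locus table (see [locus_table()]).
#' @export
read_locus_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "linkage_group", "cM")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("locus map lacks columns: ",
                         paste(miss, collapse = ", "))
  locus_table(df$locus_id, df$linkage_group, df$cM)
}

#' @rdname read_locus_map
#' @param loci A locus table to write.
#' @export
write_locus_map <- function(loci, path) {
  utils::write.csv(data.frame(locus_id = loci$locus_id,
                              linkage_group = loci$linkage_group,
                              cM = loci$map_pos),
                   path, row.names = FALSE)
}

#' Read a haul observation table
#'
#' CSV columns: `haul_id`, `period_id`, `utm_x`, `area`, `life_stage`,
#' `east_count`, `n_fish`, `salinity`, `oxygen`, `temperature`.
#'
#' @param path File path.
#' @return A `data.frame` of haul observations.
#' @export
read_haul_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("haul_id", "period_id", "utm_x", "life_stage", "east_count",
            "n_fish", "salinity", "oxygen", "temperature")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("haul table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$east_count < 0 | df$east_count > df$n_fish)) {
    stop("east_count outside [0, n_fish]")
  }
  df
}
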