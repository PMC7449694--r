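#' Default column-name mapping for summary-statistics files
#'
#' Standard field -> file column name. Override entries to read files with
#' other headers, e.g. `sumstatsDialect(snp = "rsid", beta = "b")`.
#'
#' @param ... named overrides of the default mapping.
#' @return named character vector over fields snp, effect_allele,
#'   other_allele, eaf, beta, se, p, n.
#' @export
#' @examples
#' sumstatsDialect(snp = "variant_id", se = "standard_error")
sumstatsDialect <- function(...) {
  d <- c(snp = "snp", effect_allele = "effect_allele",
         other_allele = "other_allele", eaf = "eaf", beta = "beta",
         se = "se", p = "p", n = "n")
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad))
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

#' Construct a SummaryStats object
#'
#' @param records data.frame; must contain columns `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`; `eaf`, `p`, `n` are filled with NA when
#'   absent.
#' @param trait trait name.
#' @param sex `"male"`, `"female"` or `"combined"`.
#' @param scale `"linear"` or `"logodds"`.
#' @return a validated [SummaryStats-class] object.
#' @export
#' @examples
#' SummaryStats(data.frame(snp = "rs1", effect_allele = "A",
#'   other_allele = "G", beta = 0.1, se = 0.02), trait = "ldl", sex = "male")
SummaryStats <- function(records, trait = NA_character_, sex = "combined",
                         scale = c("linear", "logodds")) {
  scale <- match.arg(scale)
  for (col in c("eaf", "p", "n"))
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  records <- records[, c("snp", "effect_allele", "other_allele", "eaf",
                         "beta", "se", "p", "n")]
  records$snp <- as.character(records$snp)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  rownames(records) <- NULL
  new("SummaryStats", records = records, trait = trait, sex = sex,
      scale = scale)
}

#' Construct an LDMatrix
#'
#' @param snps rsIDs, in matrix order.
#' @param rho square signed-correlation matrix.
#' @return a validated [LDMatrix-class] object.
#' @export
LDMatrix <- function(snps, rho) {
  rho <- as.matrix(rho)
  dimnames(rho) <- NULL
  new("LDMatrix", snps = as.character(snps), rho = rho)
}

.detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads tab- (default) or comma-delimited text with a header; the delimiter
#' is auto-detected from the header line. Rows violating record invariants
#' (non-positive SE, allele problems, out-of-range frequencies) are rejected
#' together, citing their line numbers.
#'
#' @param path file path.
#' @param dialect column-name mapping from [sumstatsDialect()].
#' @param trait,sex,scale metadata attached to the result.
#' @param onInvalid `"error"` (default) stops on any invalid row; `"drop"`
#'   removes them and records them in `attr(x, "rejected")`.
#' @return a [SummaryStats-class] object.
#' @export
readSumstats <- function(path, dialect = sumstatsDialect(),
                         trait = NA_character_, sex = "combined",
                         scale = c("linear", "logodds"),
                         onInvalid = c("error", "drop")) {
  scale <- match.arg(scale)
  onInvalid <- match.arg(onInvalid)
  sep <- .detectSep(path)
  # colClasses character: a lone T or F allele must never become a logical
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  req <- c("snp", "effect_allele", "other_allele", "beta", "se")
  for (field in req)
    if (!dialect[[field]] %in% names(raw))
      stop(sprintf("format error: required column '%s' (field '%s') not found",
                   dialect[[field]], field))
  pick <- function(field) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]] else NA
  }
  rec <- data.frame(snp = as.character(pick("snp")),
                    effect_allele = toupper(as.character(pick("effect_allele"))),
                    other_allele = toupper(as.character(pick("other_allele"))),
                    eaf = as.numeric(pick("eaf")),
                    beta = as.numeric(pick("beta")),
                    se = as.numeric(pick("se")),
                    p = as.numeric(pick("p")),
                    n = as.numeric(pick("n")),
                    stringsAsFactors = FALSE)
  bad <- .invalidRows(rec)
  if (length(bad$rows)) {
    # file line = data row + header line
    msg <- sprintf("invalid row(s) in %s: %s", path,
                   paste(sprintf("row %d, file line %d (%s)", bad$rows,
                                 bad$rows + 1L, bad$why),
                         collapse = "; "))
    if (onInvalid == "error") stop("validation error: ", msg)
    warning(msg)
    rejected <- rec[bad$rows, , drop = FALSE]
    rec <- rec[-bad$rows, , drop = FALSE]
  }
  out <- SummaryStats(rec, trait = trait, sex = sex, scale = scale)
  if (onInvalid == "drop" && length(bad$rows))
    attr(out, "rejected") <- cbind(line = bad$rows + 1L, rejected)
  out
}

.invalidRows <- function(rec) {
  why <- character(nrow(rec))
  flag <- function(idx, reason) {
    why[idx] <<- ifelse(nzchar(why[idx]), paste(why[idx], reason, sep = "; "),
                        reason)
  }
  flag(which(!is.na(rec$se) & rec$se <= 0), "se <= 0")
  flag(which(is.na(rec$se)), "missing se")
  flag(which(is.na(rec$beta)), "missing beta")
  ok_a <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  flag(which(!ok_a(rec$effect_allele) | !ok_a(rec$other_allele) |
               rec$effect_allele == rec$other_allele), "bad allele pair")
  flag(which(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1)), "eaf outside [0,1]")
  flag(which(!is.na(rec$p) & (rec$p < 0 | rec$p > 1)), "p outside [0,1]")
  rows <- which(nzchar(why))
  list(rows = rows, why = why[rows])
}

.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 12, scientific = FALSE,
                                   trim = TRUE)
  }, character(1))
  out
}

#' Write summary statistics as tab-delimited text
#'
#' Numeric columns are written with 12 significant digits so a write/read
#' round trip preserves values.
#'
#' @param x a [SummaryStats-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path) {
  rec <- x@records
  for (col in c("eaf", "beta", "se", "p", "n"))
    rec[[col]] <- .fmtNum(rec[[col]])
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an LD correlation matrix
#'
#' Square tab- or comma-delimited matrix of signed correlations with rsIDs
#' both as the header row and the first column.
#'
#' @param path file path.
#' @return [readLDMatrix()]: an [LDMatrix-class] object.
#' @export
readLDMatrix <- function(path) {
  sep <- .detectSep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(raw)
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row and column rsIDs disagree")
  # symmetrize away round-tripped representation noise only
  m <- (m + t(m)) / 2
  diag(m) <- 1
  LDMatrix(rownames(m), m)
}

#' @rdname readLDMatrix
#' @param x an [LDMatrix-class] object.
#' @export
writeLDMatrix <- function(x, path) {
  m <- ldRho(x)
  df <- data.frame(snp = rownames(m),
                   apply(m, 2, .fmtNum),
                   check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
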