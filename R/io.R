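# Tabular dialect readers/writers. Every table the pipeline touches is
# tab-separated UTF-8 with a fixed header; reals are serialized with the
# shortest round-trip representation so write -> read is exact.

.dialects <- list(
  associations = list(
    cols = c("rsid", "genes", "p_value", "odds_ratio", "source_id"),
    num = c("p_value", "odds_ratio"), lgl = character()),
  ld_proxies = list(
    cols = c("index_rsid", "proxy_rsid", "r2", "proxy_genes"),
    num = "r2", lgl = character()),
  missense = list(cols = "gene", num = character(), lgl = character()),
  eqtl = list(
    cols = c("gene", "tissue", "significant"),
    num = character(), lgl = "significant"),
  go = list(
    cols = c("gene", "term", "namespace"),
    num = character(), lgl = character()),
  edges = list(
    cols = c("gene_a", "gene_b", "confidence"),
    num = "confidence", lgl = character()),
  drug_targets = list(
    cols = c("drug", "gene", "action_known", "organism", "groups"),
    num = character(), lgl = "action_known"),
  connectivity = list(
    cols = c("drug", "score"), num = "score", lgl = character()),
  evidence = list(
    cols = c("gene", "missense", "cis_eqtl", "go_bp", "go_cc", "go_mf", "kegg"),
    num = character(),
    lgl = c("missense", "cis_eqtl", "go_bp", "go_cc", "go_mf", "kegg")),
  genes = list(cols = "gene", num = character(), lgl = character())
)

.drug_groups <- c("approved", "investigational", "experimental", "other")

#' Read a pipeline input table
#'
#' Parses and validates one of the fixed tab-separated dialects used by the
#' pipeline. Every row is checked against the dialect's invariants; a
#' violation raises an error naming the offending line. Readers never drop
#' or reorder rows.
#'
#' @param path path to a TSV (or GMT) file.
#' @param format_name one of `"associations"`, `"ld_proxies"`, `"missense"`,
#'   `"eqtl"`, `"go"`, `"gmt"`, `"edges"`, `"drug_targets"`,
#'   `"connectivity"`, `"evidence"`, `"genes"`.
#' @return a `data.frame` with the dialect's columns (for `"gmt"`, a named
#'   list mapping set id to a character vector of gene symbols).
#' @export
read_table <- function(path, format_name) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (identical(format_name, "gmt")) {
    sets <- fgsea::gmtPathways(path)
    return(lapply(sets, norm_symbols))
  }
  d <- .dialects[[format_name]]
  if (is.null(d)) stop("unknown table format: ", format_name)
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8")
  missing_cols <- setdiff(d$cols, names(df))
  if (length(missing_cols))
    stop(sprintf("format '%s': missing column(s) %s in %s", format_name,
                 paste(missing_cols, collapse = ", "), path))
  extra <- setdiff(names(df), d$cols)
  if (length(extra))
    stop(sprintf("format '%s': unknown column(s) %s in %s", format_name,
                 paste(extra, collapse = ", "), path))
  df <- df[, d$cols, drop = FALSE]
  for (cn in d$num) {
    raw <- df[[cn]]
    val <- suppressWarnings(as.numeric(ifelse(raw %in% c("", "NA"), NA, raw)))
    bad <- which(!(raw %in% c("", "NA")) & is.na(val))
    if (length(bad))
      stop(sprintf("format '%s' line %d: non-numeric value '%s' in column %s",
                   format_name, bad[1] + 1L, raw[bad[1]], cn))
    df[[cn]] <- val
  }
  for (cn in d$lgl) {
    raw <- toupper(df[[cn]])
    bad <- which(!(raw %in% c("TRUE", "FALSE")))
    if (length(bad))
      stop(sprintf("format '%s' line %d: column %s must be TRUE/FALSE",
                   format_name, bad[1] + 1L, cn))
    df[[cn]] <- raw == "TRUE"
  }
  rownames(df) <- NULL
  validate_dialect(df, format_name)
}

row_err <- function(format_name, i, msg) {
  stop(sprintf("format '%s' line %d: %s", format_name, i + 1L, msg),
       call. = FALSE)
}

validate_dialect <- function(df, format_name) {
  n <- nrow(df)
  fail <- function(ok, msg) {
    bad <- which(!ok)
    if (length(bad)) row_err(format_name, bad[1], msg)
  }
  switch(format_name,
    associations = {
      fail(grepl("^rs[0-9]+$", df$rsid), "rsid must match rs<digits>")
      fail(df$p_value > 0 & df$p_value <= 1, "p_value must be in (0, 1]")
      fail(is.na(df$odds_ratio) | df$odds_ratio > 0,
           "odds_ratio must be positive when present")
      df$genes <- normalize_gene_cell(df$genes)
    },
    ld_proxies = {
      fail(grepl("^rs[0-9]+$", df$index_rsid) & grepl("^rs[0-9]+$", df$proxy_rsid),
           "rsids must match rs<digits>")
      fail(df$r2 >= 0 & df$r2 <= 1, "r2 must be in [0, 1]")
      fail(df$index_rsid != df$proxy_rsid,
           "index and proxy rsid must differ")
      df$proxy_genes <- normalize_gene_cell(df$proxy_genes)
    },
    missense = , genes = {
      fail(nzchar(trimws(df$gene)), "gene symbol must be non-empty")
      df$gene <- toupper(trimws(df$gene))
    },
    eqtl = {
      fail(nzchar(trimws(df$gene)), "gene symbol must be non-empty")
      df$gene <- toupper(trimws(df$gene))
      df$tissue <- trimws(df$tissue)
    },
    go = {
      fail(nzchar(trimws(df$gene)), "gene symbol must be non-empty")
      df$gene <- toupper(trimws(df$gene))
      fail(df$namespace %in% c("BP", "CC", "MF"),
           "namespace must be one of BP, CC, MF")
    },
    edges = {
      df$gene_a <- toupper(trimws(df$gene_a))
      df$gene_b <- toupper(trimws(df$gene_b))
      fail(nzchar(df$gene_a) & nzchar(df$gene_b), "gene symbols must be non-empty")
      fail(df$gene_a != df$gene_b, "self-loop edge")
      fail(df$confidence >= 0 & df$confidence <= 1,
           "confidence must be in [0, 1]")
      # undirected: store each pair with gene_a < gene_b
      swap <- df$gene_a > df$gene_b
      tmp <- df$gene_a[swap]
      df$gene_a[swap] <- df$gene_b[swap]
      df$gene_b[swap] <- tmp
    },
    drug_targets = {
      fail(nzchar(trimws(df$drug)), "drug name must be non-empty")
      df$gene <- toupper(trimws(df$gene))
      fail(nzchar(df$gene), "gene symbol must be non-empty")
      grp <- strsplit(df$groups, "\\|")
      ok <- vapply(grp, function(g) {
        g <- trimws(tolower(g))
        length(g) > 0 && all(g %in% .drug_groups)
      }, logical(1))
      fail(ok, sprintf("groups must be a non-empty |-joined subset of {%s}",
                       paste(.drug_groups, collapse = ", ")))
      df$groups <- vapply(grp, function(g)
        paste(unique(trimws(tolower(g))), collapse = "|"), character(1))
    },
    connectivity = {
      fail(nzchar(trimws(df$drug)), "drug name must be non-empty")
      fail(df$score >= -100 & df$score <= 100,
           "score must be in [-100, 100]")
    },
    evidence = {
      fail(nzchar(trimws(df$gene)), "gene symbol must be non-empty")
      df$gene <- toupper(trimws(df$gene))
    }
  )
  df
}

#' Write a pipeline table
#'
#' Inverse of [read_table()]: writes tab-separated UTF-8 with the dialect's
#' fixed column order. Numeric columns use the shortest decimal
#' representation that reparses to the identical double, so round-trips are
#' record-for-record exact.
#'
#' @param records data.frame of validated records (named list of character
#'   vectors for `"gmt"`).
#' @param path output file path.
#' @param format_name dialect name, see [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format_name) {
  if (identical(format_name, "gmt")) {
    if (!is.list(records) || is.data.frame(records) ||
        (length(records) && is.null(names(records))))
      stop("gmt records must be a named list of gene vectors")
    lines <- vapply(seq_along(records), function(i)
      paste(c(names(records)[i], "na", records[[i]]), collapse = "\t"),
      character(1))
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  d <- .dialects[[format_name]]
  if (is.null(d)) stop("unknown table format: ", format_name)
  if (!is.data.frame(records)) stop("records must be a data.frame")
  missing_cols <- setdiff(d$cols, names(records))
  if (length(missing_cols))
    stop(sprintf("format '%s': records lack column(s) %s", format_name,
                 paste(missing_cols, collapse = ", ")))
  out <- records[, d$cols, drop = FALSE]
  for (cn in d$num) out[[cn]] <- fmt_num(as.numeric(out[[cn]]))
  for (cn in d$lgl) {
    if (!is.logical(records[[cn]]))
      stop(sprintf("format '%s': column %s must be logical", format_name, cn))
    out[[cn]] <- ifelse(records[[cn]], "TRUE", "FALSE")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}
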