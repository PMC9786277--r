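# Small shared helpers: numeric serialization, gene-symbol normalization,
# half-up rounding.

#' Round half away from zero
#'
#' Base `round()` uses banker's rounding (round-half-to-even); reported
#' coverage percentages use the conventional half-up rule, so 21.05 prints
#' as 21.1 and not 21.0.
#'
#' @param x numeric vector (non-negative in all pipeline uses).
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Shortest decimal representation that reparses to the exact double.
# Keeps written tables human-readable ("0.8", "88.76") while making
# read(write(x)) bit-stable.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

# Tokens that mark an absent gene mapping in catalog exports.
.unknown_gene_tokens <- c("", "NOT KNOWN", "NR", "NONE", "NA")

# Split a mapped-gene cell on commas, semicolons and " - " (intergenic
# flanking-gene separator), trim, uppercase, dedupe preserving order.
split_genes <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(character())
  toks <- toupper(trimws(strsplit(s, ",|;|\\s-\\s")[[1]]))
  toks <- toks[!(toks %in% .unknown_gene_tokens)]
  unique(toks)
}

# Canonical stored form of a gene cell: ", "-joined normalized symbols.
normalize_gene_cell <- function(s) {
  vapply(s, function(x) paste(split_genes(x), collapse = ", "), character(1),
         USE.NAMES = FALSE)
}

norm_symbols <- function(x) unique(toupper(trimws(x[nzchar(trimws(x))])))

`%||%` <- function(a, b) if (is.null(a)) b else a
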