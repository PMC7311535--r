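#' @name iupac
#' @title IUPAC nucleotide code utilities
#' @description Expansion of IUPAC ambiguity codes to the A/C/G/T bases each
#'   one stands for. `N` in a *subject* sequence is never treated as a match:
#'   assembly gaps must not spawn restriction sites.
#' @keywords internal
NULL

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse-complement an IUPAC string
#' @param x character vector of IUPAC nucleotide strings.
#' @return character vector of reverse complements.
#' @keywords internal
iupac_revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(IUPAC_COMPLEMENT[b])), collapse = "")
  }, character(1))
}

# 4 x 15 logical lookup: does concrete base (row) satisfy IUPAC code (col)?
iupac_match_table <- local({
  codes <- names(IUPAC_CODES)
  m <- matrix(FALSE, nrow = 4, ncol = length(codes),
              dimnames = list(c("A", "C", "G", "T"), codes))
  for (code in codes) m[IUPAC_CODES[[code]], code] <- TRUE
  m
})

#' Restriction enzyme definition
#'
#' An enzyme is a named recognition sequence (IUPAC codes allowed, e.g.
#' ApoI = `R^AATTY`) together with the 0-based offset of the top-strand cut
#' point within the site (PstI `CTGCA^G` has offset 5).
#'
#' @param name short enzyme label, e.g. `"PstI"`.
#' @param recognition IUPAC recognition sequence (non-empty).
#' @param cut_offset integer in `[0, nchar(recognition)]`: position of the
#'   top-strand cut within the site.
#' @return an object of class `"enzyme"`.
#' @examples
#' enzyme("PstI", "CTGCAG", 5)
#' enzyme("ApoI", "RAATTY", 1)
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(as.character(recognition))
  if (!nzchar(recognition)) {
    stop("enzyme '", name, "': recognition sequence must be non-empty")
  }
  bad <- setdiff(strsplit(recognition, "")[[1]], names(IUPAC_CODES))
  if (length(bad)) {
    stop("enzyme '", name, "': invalid IUPAC code(s) in recognition: ",
         paste(bad, collapse = ", "))
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0 || cut_offset > nchar(recognition)) {
    stop("enzyme '", name, "': cut_offset must lie within the recognition site")
  }
  structure(
    list(name = as.character(name), recognition = recognition,
         cut_offset = cut_offset),
    class = "enzyme"
  )
}

#' @export
print.enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("<enzyme> %s  %s\n", x$name, site))
  invisible(x)
}

#' Is a recognition sequence palindromic under IUPAC complement?
#' @param enz an [enzyme()].
#' @return logical.
#' @export
is_palindromic <- function(enz) {
  stopifnot(inherits(enz, "enzyme"))
  identical(enz$recognition, iupac_revcomp(enz$recognition))
}

#' Load the packaged restriction-enzyme catalog
#'
#' Catalog of candidate enzymes for RR-seq library design. Admission rules
#' for the catalog: recognition sites of at most six base pairs (more, hence
#' smaller, fragments), no two entries with the same recognition sequence,
#' and methylation-insensitive high-fidelity enzymes only. The matcher
#' itself supports IUPAC ambiguity codes (ApoI = `R^AATTY`).
#'
#' @param path optional path to a TSV with columns `name`, `recognition`,
#'   `cut_offset`; defaults to the catalog shipped with the package.
#' @return named list of [enzyme()] objects.
#' @examples
#' cat <- enzyme_catalog()
#' cat$PstI
#' @export
enzyme_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes.tsv", package = "mutread",
                        mustWork = TRUE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("name", "recognition", "cut_offset")
  if (!all(needed %in% names(tab))) {
    stop("enzyme catalog must have columns: ", paste(needed, collapse = ", "))
  }
  enzymes <- mapply(enzyme, tab$name, tab$recognition, tab$cut_offset,
                    SIMPLIFY = FALSE)
  names(enzymes) <- tab$name
  validate_catalog(enzymes)
  enzymes
}

# catalog admission rules: <= 6 bp sites, no duplicate recognition sequences
# (ambiguous recognitions may still subsume another enzyme's concrete site,
# as ApoI RAATTY subsumes EcoRI GAATTC)
validate_catalog <- function(enzymes) {
  for (e in enzymes) {
    if (nchar(e$recognition) > 6L) {
      stop("catalog enzyme '", e$name, "': recognition longer than 6 bp")
    }
  }
  recs <- vapply(enzymes, `[[`, character(1), "recognition")
  if (anyDuplicated(recs)) {
    stop("catalog contains duplicate recognition sequences: ",
         paste(unique(recs[duplicated(recs)]), collapse = ", "))
  }
  invisible(enzymes)
}

# all concrete A/C/G/T sequences matching an IUPAC string
expand_iupac <- function(recognition) {
  sets <- IUPAC_CODES[strsplit(toupper(recognition), "")[[1]]]
  apply(do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE)), 1L,
        function(row) paste(rev(row), collapse = ""))
}

#' Look an enzyme up by name, accepting enzyme objects as-is
#' @param x an [enzyme()] or a catalog name.
#' @param catalog named list from [enzyme_catalog()].
#' @return an [enzyme()].
#' @keywords internal
as_enzyme <- function(x, catalog = NULL) {
  if (inherits(x, "enzyme")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (is.null(catalog)) catalog <- enzyme_catalog()
    if (!x %in% names(catalog)) stop("unknown catalog enzyme: ", x)
    return(catalog[[x]])
  }
  stop("expected an enzyme object or a catalog enzyme name")
}
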