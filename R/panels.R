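## Commercial Y-STR panel definitions and locus-name normalization.

# Canonical locus -> expected copy number, per kit. Multi-copy loci
# (DYS385a/b, DYF387S1a/b, DYS527a/b) count as two loci in kit sizes.
.yfiler_loci <- c(
  DYS19 = 1L, DYS389I = 1L, DYS389II = 1L, DYS390 = 1L, DYS391 = 1L,
  DYS392 = 1L, DYS393 = 1L, DYS437 = 1L, DYS438 = 1L, DYS439 = 1L,
  DYS448 = 1L, DYS456 = 1L, DYS458 = 1L, DYS635 = 1L, YGATAH4 = 1L,
  `DYS385a/b` = 2L)

.ppy23_extra <- c(DYS481 = 1L, DYS533 = 1L, DYS549 = 1L, DYS570 = 1L,
                  DYS576 = 1L, DYS643 = 1L)

.yfiler_plus_extra <- c(DYS449 = 1L, DYS460 = 1L, DYS481 = 1L, DYS518 = 1L,
                        DYS533 = 1L, DYS570 = 1L, DYS576 = 1L, DYS627 = 1L,
                        `DYF387S1a/b` = 2L)

.platinum_extra <- c(DYS388 = 1L, DYS444 = 1L, DYS447 = 1L, DYS557 = 1L,
                     DYS593 = 1L, DYS596 = 1L, DYS645 = 1L,
                     `DYS527a/b` = 2L)

# the 38-locus kit covers the union of the three smaller panels
.dedupe <- function(x) x[!duplicated(names(x))]
.builtin_panel_copies <- list(
  yfiler          = .yfiler_loci,
  ppy23           = c(.yfiler_loci, .ppy23_extra),
  yfiler_plus     = c(.yfiler_loci, .yfiler_plus_extra),
  yfiler_platinum = .dedupe(c(.yfiler_loci, .ppy23_extra,
                              .yfiler_plus_extra, .platinum_extra))
)

# published tables spell locus names in many ways
.locus_aliases <- c(
  "DYS389-1"   = "DYS389I",   "DYS389-2"  = "DYS389II",
  "DYS3891"    = "DYS389I",   "DYS3892"   = "DYS389II",
  "YGATA-H4"   = "YGATAH4",   "Y-GATA-H4" = "YGATAH4",  "GATAH4" = "YGATAH4",
  "DYS385"     = "DYS385a/b", "DYS385AB"  = "DYS385a/b",
  "DYS385A/B"  = "DYS385a/b",
  "DYF387S1"   = "DYF387S1a/b", "DYF387S1A/B" = "DYF387S1a/b",
  # the a/b suffix kit literature also renders DYF387S1 as DYS387S1
  "DYS387S1"   = "DYF387S1a/b", "DYS387S1A/B" = "DYF387S1a/b",
  "DYS527"     = "DYS527a/b", "DYS527A/B" = "DYS527a/b"
)

#' Normalize a Y-STR locus name
#'
#' Case-insensitive; maps common spelling variants (e.g. `"DYS389-2"`,
#' `"YGATA-H4"`, `"DYS387S1a/b"`) to the canonical names used throughout the
#' package.
#'
#' @param x character vector of locus names.
#' @return character vector of canonical names.
#' @export
#' @examples
#' normalize_locus(c("dys389ii", "YGATA-H4", "DYS387S1a/b"))
normalize_locus <- function(x) {
  canon <- names(.builtin_panel_copies$yfiler_platinum)
  up <- toupper(trimws(x))
  lut <- stats::setNames(canon, toupper(canon))
  alias <- stats::setNames(unname(.locus_aliases), toupper(names(.locus_aliases)))
  out <- ifelse(up %in% names(lut), lut[up],
                ifelse(up %in% names(alias), alias[up], NA_character_))
  # unknown names pass through unchanged (custom panels are allowed)
  ifelse(is.na(out), trimws(x), out)
}

#' Construct or fetch a Y-STR panel
#'
#' A panel is an ordered locus set with the expected number of allele copies
#' per locus. The four built-in panels mirror the common commercial kits:
#' `"yfiler"` (17 loci), `"ppy23"` (23), `"yfiler_plus"` (27) and
#' `"yfiler_platinum"` (38), counting each multi-copy locus
#' (DYS385a/b, DYF387S1a/b, DYS527a/b) as two.
#'
#' @param name one of the built-in panel names, or a custom name when `loci`
#'   is given.
#' @param loci optional character vector of locus names for a custom panel.
#' @param copies optional integer vector (1 or 2) parallel to `loci`;
#'   defaults to 1.
#' @return an object of class `"y_panel"`: list with `name`, `loci`,
#'   `copies` (named integer) and `size` (sum of copies).
#' @export
#' @examples
#' ypanel("yfiler")$size  # 17
ypanel <- function(name, loci = NULL, copies = NULL) {
  if (is.null(loci)) {
    name <- match.arg(tolower(name), names(.builtin_panel_copies))
    cp <- .builtin_panel_copies[[name]]
  } else {
    loci <- normalize_locus(loci)
    if (anyDuplicated(loci)) stop("duplicated loci in custom panel")
    if (is.null(copies)) copies <- rep(1L, length(loci))
    cp <- stats::setNames(as.integer(copies), loci)
  }
  stopifnot(all(cp %in% 1:2))
  structure(list(name = name, loci = names(cp), copies = cp,
                 size = sum(cp)),
            class = "y_panel")
}

#' @export
print.y_panel <- function(x, ...) {
  cat(sprintf("Y-STR panel '%s': %d loci (%d columns)\n",
              x$name, x$size, length(x$loci)))
  cat(paste(strwrap(paste(x$loci, collapse = ", "), width = 70), collapse = "\n"),
      "\n")
  invisible(x)
}

#' List built-in panel names
#' @return character vector.
#' @export
ypanels <- function() names(.builtin_panel_copies)

#' Read / write a panel definition file
#'
#' Tab-separated, two columns `locus` and `copies`.
#'
#' @param path file path.
#' @param name panel name to attach on read.
#' @return `read_panel` returns a `"y_panel"`; `write_panel` its path,
#'   invisibly.
#' @export
read_panel <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("locus", "copies") %in% names(df)))
    stop("panel file needs columns 'locus' and 'copies'")
  ypanel(name, loci = df$locus, copies = df$copies)
}

#' @rdname read_panel
#' @param panel a `"y_panel"` object.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(
    data.frame(locus = panel$loci, copies = unname(panel$copies)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
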