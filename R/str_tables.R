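## STR genotype tables: one row per male sample, one list-column of repeat
## values per locus. An empty numeric vector is a null call.

new_str_profiles <- function(df) {
  structure(df, class = c("str_profiles", "data.frame"))
}

#' Read a Y-STR genotype table
#'
#' Delimited text with header `sample_id, population, <locus...>`. Multi-copy
#' cells hold delimited allele lists (default `"-"`; `","` and `"/"` are also
#' accepted on read). Microvariant alleles use a decimal repeat value such as
#' `"38.2"`. An empty cell is a null call.
#'
#' @param path file path (TSV or CSV; the delimiter is sniffed from the
#'   header unless `sep` is given).
#' @param panel optional `"y_panel"`; when given, every locus column must
#'   belong to the panel and columns are ordered to match it.
#' @param sep field delimiter, `"\t"` or `","`; `NULL` to sniff.
#' @param allele_sep intra-cell allele delimiter written by [write_str_table()].
#' @return an object of class `"str_profiles"`: a data frame with columns
#'   `sample_id`, `population` and one list-column of sorted numeric repeat
#'   values per locus.
#' @export
read_str_table <- function(path, panel = NULL, sep = NULL, allele_sep = "-") {
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3 || !identical(tolower(names(raw)[1:2]),
                                  c("sample_id", "population")))
    stop("STR table must start with columns 'sample_id', 'population'")
  loci <- normalize_locus(names(raw)[-(1:2)])
  if (anyDuplicated(loci))
    stop("duplicated locus columns after name normalization: ",
         paste(loci[duplicated(loci)], collapse = ", "))
  if (!is.null(panel)) {
    unknown <- setdiff(loci, panel$loci)
    if (length(unknown))
      stop("locus column(s) not in panel '", panel$name, "': ",
           paste(unknown, collapse = ", "))
  }
  out <- data.frame(sample_id = raw[[1]], population = raw[[2]],
                    stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    col <- raw[[j + 2L]]
    out[[loci[j]]] <- lapply(seq_along(col), function(i) {
      tryCatch(parse_cell(col[i], sep = allele_sep),
               error = function(e) stop(
                 "sample '", raw[[1]][i], "', locus ", loci[j], ": ",
                 conditionMessage(e), call. = FALSE))
    })
  }
  if (!is.null(panel)) {
    keep <- intersect(panel$loci, loci)
    out <- out[, c("sample_id", "population", keep)]
  }
  new_str_profiles(out)
}

#' @rdname read_str_table
#' @param profiles a `"str_profiles"` object.
#' @export
write_str_table <- function(profiles, path, sep = "\t", allele_sep = "-") {
  loci <- str_loci(profiles)
  out <- data.frame(sample_id = profiles$sample_id,
                    population = profiles$population,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (l in loci)
    out[[l]] <- vapply(profiles[[l]], format_cell, character(1),
                       sep = allele_sep)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Locus columns of an STR profile table
#' @param profiles a `"str_profiles"` object.
#' @return character vector of locus names.
#' @export
str_loci <- function(profiles)
  setdiff(names(profiles), c("sample_id", "population", "dys389b_flag"))

#' Restrict profiles to a panel's loci
#'
#' Subsetting is idempotent: restricting twice to the same panel is a no-op.
#' @inheritParams write_str_table
#' @param panel a `"y_panel"`.
#' @return `"str_profiles"` with only the panel's loci, in panel order.
#' @export
subset_panel <- function(profiles, panel) {
  keep <- intersect(panel$loci, str_loci(profiles))
  new_str_profiles(profiles[, c("sample_id", "population", keep)])
}

#' @export
print.str_profiles <- function(x, ...) {
  cat(sprintf("Y-STR profiles: %d samples, %d loci, %d population(s)\n",
              nrow(x), length(str_loci(x)),
              length(unique(x$population))))
  invisible(x)
}

#' Derive the DYS389b repeat count
#'
#' The DYS389II amplicon physically contains DYS389I, so the distal repeat
#' stretch is `DYS389b = DYS389II - DYS389I`. Samples with a missing or
#' multi-valued call at either parent locus, or a non-positive difference,
#' are flagged (column `dys389b_flag`) and should be excluded from the
#' network stage.
#'
#' @param profiles a `"str_profiles"` object with DYS389I and DYS389II.
#' @return the profiles with an added `DYS389b` list-column and a logical
#'   `dys389b_flag` column (`TRUE` = unusable).
#' @export
derive_dys389b <- function(profiles) {
  if (!all(c("DYS389I", "DYS389II") %in% names(profiles)))
    stop("profiles lack DYS389I and/or DYS389II")
  n <- nrow(profiles)
  b <- vector("list", n)
  flag <- logical(n)
  for (i in seq_len(n)) {
    a1 <- profiles$DYS389I[[i]]
    a2 <- profiles$DYS389II[[i]]
    if (length(a1) != 1L || length(a2) != 1L ||
        a1 != round(a1) || a2 != round(a2)) {
      b[[i]] <- numeric(0); flag[i] <- TRUE
    } else {
      d <- a2 - a1
      b[[i]] <- d
      flag[i] <- d <= 0  # DYS389II must exceed DYS389I
    }
  }
  profiles$DYS389b <- b
  profiles$dys389b_flag <- flag
  new_str_profiles(profiles)
}
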