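## Y-SNP marker-state tables: one row per sample, one column per binary
## marker, states A (ancestral), D (derived), N (no call).

#' Read a Y-SNP marker-state table
#'
#' Delimited text with header `sample_id, population, <marker...>`; cell
#' values `A` (ancestral), `D` (derived) or `N` (no call; empty cells also
#' read as `N`).
#'
#' @param path file path (TSV or CSV).
#' @param sep field delimiter; `NULL` to sniff from the header.
#' @return an object of class `"snp_profiles"`: a data frame with character
#'   marker columns.
#' @export
read_snp_table <- function(path, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3 || !identical(tolower(names(raw)[1:2]),
                                  c("sample_id", "population")))
    stop("SNP table must start with columns 'sample_id', 'population'")
  for (j in seq(3, ncol(raw))) {
    v <- toupper(trimws(raw[[j]]))
    v[!nzchar(v)] <- "N"
    bad <- !v %in% c("A", "D", "N")
    if (any(bad))
      stop("invalid SNP state '", raw[[j]][which(bad)[1]], "' at marker ",
           names(raw)[j], ", sample '", raw[[1]][which(bad)[1]], "'")
    raw[[j]] <- v
  }
  structure(raw, class = c("snp_profiles", "data.frame"))
}

#' @rdname read_snp_table
#' @param profiles a `"snp_profiles"` object.
#' @export
write_snp_table <- function(profiles, path, sep = "\t") {
  utils::write.table(as.data.frame(profiles), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker columns of a SNP profile table
#' @param profiles a `"snp_profiles"` object.
#' @return character vector of marker names.
#' @export
snp_markers <- function(profiles)
  setdiff(names(profiles), c("sample_id", "population"))

#' @export
print.snp_profiles <- function(x, ...) {
  cat(sprintf("Y-SNP profiles: %d samples, %d markers, %d population(s)\n",
              nrow(x), length(snp_markers(x)), length(unique(x$population))))
  invisible(x)
}
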