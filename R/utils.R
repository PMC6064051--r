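#' @keywords internal
#' @importFrom utils read.delim write.table
read_tsv_file <- function(path, required = NULL, comment.char = "#") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = comment.char,
                          check.names = FALSE, na.strings = c("NA", ""))
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop("missing required column(s) in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' @keywords internal
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Internal: empty data.frame with the given character columns
empty_df <- function(cols) {
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

# Internal: parse a short-form protein change (HGVS-p without the "p." prefix).
# Returns a list with ref, pos (first affected codon), alt and ok flag.
parse_protein_change <- function(pc) {
  pc <- sub("^p\\.", "", as.character(pc))
  out <- list(ref = NA_character_, pos = NA_integer_, alt = NA_character_,
              ok = FALSE, raw = pc)
  if (is.na(pc) || !nzchar(pc)) return(out)
  # missense: V600E
  m <- regmatches(pc, regexec("^([A-Z])([0-9]+)([A-Z*])$", pc))[[1]]
  if (length(m) == 4L) {
    out$ref <- m[2]; out$pos <- as.integer(m[3]); out$alt <- m[4]; out$ok <- TRUE
    return(out)
  }
  # indel / delins / fs / duplication etc: take first residue mentioned
  m <- regmatches(pc, regexec("^([A-Z])([0-9]+)", pc))[[1]]
  if (length(m) == 3L) {
    out$ref <- m[2]; out$pos <- as.integer(m[3]); out$ok <- TRUE
    return(out)
  }
  out
}
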