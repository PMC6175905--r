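# File formats: FASTA (via Biostrings), regions TSV, score-track TSV,
# serialized tree models.  Coordinates on disk are 1-based inclusive,
# matching the in-memory convention.

#' Read antigens from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return List of [antigen()] objects in file order, with empty region
#'   tables.  Sequences are uppercased; non-canonical residues are an
#'   error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  ans <- lapply(seq_along(ss), function(i)
    antigen(ids[i], as.character(ss[[i]])))
  names(ans) <- ids
  ans
}

#' Write antigens to a FASTA file
#'
#' @param antigens List of [antigen()] objects.
#' @param path Output path.
#' @export
write_fasta <- function(antigens, path) {
  antigens <- as_antigen_list(antigens)
  ss <- Biostrings::AAStringSet(vapply(antigens, `[[`, "", "sequence"))
  names(ss) <- vapply(antigens, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

as_antigen_list <- function(antigens) {
  if (inherits(antigens, "antigen")) antigens <- list(antigens)
  stopifnot(all(vapply(antigens, inherits, TRUE, "antigen")))
  names(antigens) <- vapply(antigens, `[[`, "", "id")
  antigens
}

#' Attach interval annotations from a regions TSV
#'
#' The TSV has columns `antigen_id`, `start`, `end`, `label` and
#' optionally `score`; coordinates are 1-based inclusive.  Rows that
#' reference unknown antigens, lie outside the sequence, carry inverted
#' intervals or unknown labels are rejected with an error.
#'
#' @param path Regions TSV path.
#' @param antigens List of [antigen()] objects the rows refer to.
#' @return The antigen list with regions attached.
#' @export
read_regions <- function(path, antigens) {
  antigens <- as_antigen_list(antigens)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("antigen_id", "start", "end", "label")
  if (!all(need %in% names(tab)))
    stop("regions TSV must have columns ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(tab$antigen_id), names(antigens))
  if (length(unknown))
    stop("regions reference unknown antigen(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(tab$score)) tab$score <- NA_real_
  for (id in unique(tab$antigen_id)) {
    rows <- tab[tab$antigen_id == id,
                c("start", "end", "label", "score"), drop = FALSE]
    antigens[[id]] <- set_regions(antigens[[id]], rows)
  }
  antigens
}

#' Write interval annotations to a regions TSV
#'
#' @param antigens List of [antigen()] objects (their `regions` tables
#'   are concatenated).
#' @param path Output path.
#' @export
write_regions <- function(antigens, path) {
  antigens <- as_antigen_list(antigens)
  tabs <- lapply(antigens, function(a) {
    if (!nrow(a$regions)) return(NULL)
    cbind(antigen_id = a$id, a$regions)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab))
    tab <- data.frame(antigen_id = character(), start = integer(),
                      end = integer(), label = character(),
                      score = numeric())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score tracks: read / write
#'
#' A score track assigns every residue of an antigen a score in
#' \[0, 1\] (rendered 0-100 in figures).  On disk it is a TSV with
#' columns `antigen_id`, `position`, `score`, one row per residue.
#' `read_track(write_track(t))` reproduces the track to full stored
#' precision.
#'
#' @param track Numeric vector of per-residue scores in \[0, 1\].
#' @param antigen_id Identifier the track belongs to.
#' @param path File path.
#' @param L Expected track length (optional check on read).
#' @return `read_track` returns a named list of numeric score vectors,
#'   one per antigen id present in the file.
#' @export
write_track <- function(track, antigen_id, path) {
  check_track(track)
  tab <- data.frame(antigen_id = antigen_id,
                    position = seq_along(track),
                    score = sprintf("%.17g", track))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path, L = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(score = "numeric"))
  need <- c("antigen_id", "position", "score")
  if (!all(need %in% names(tab)))
    stop("track TSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$antigen_id), function(d) {
    d <- d[order(d$position), ]
    if (!identical(as.integer(d$position), seq_len(nrow(d))))
      stop("track positions must be 1..L without gaps")
    check_track(d$score)
    if (!is.null(L) && nrow(d) != L)
      stop("track length ", nrow(d), " does not match declared length ", L)
    d$score
  })
  out
}

check_track <- function(track) {
  if (anyNA(track) || any(track < 0 | track > 1))
    stop("score track values must lie in [0, 1]")
  invisible(track)
}
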