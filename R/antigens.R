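#' @importFrom methods as
#' @importFrom stats predict runif setNames sd
#' @importFrom utils read.delim write.table head
#' @importFrom grDevices adjustcolor
NULL

# Closed label vocabulary for annotated regions.
REGION_LABELS <- c("epitope", "nonepitope", "reactive", "predicted")

#' Construct an antigen
#'
#' An antigen is a protein sequence together with 1-based inclusive
#' interval annotations (epitope / nonepitope / reactive / predicted
#' regions).  All coordinates in the package are 1-based inclusive, so a
#' region `start..end` covers exactly `end - start + 1` residues.
#'
#' @param id Character identifier.
#' @param sequence Amino-acid sequence (one-letter codes).  Lowercase is
#'   accepted and uppercased; only the 20 canonical residues are allowed.
#' @param regions Optional data frame with columns `start`, `end`,
#'   `label` and optionally `score`; see [regions()].
#' @return An object of class `"antigen"`: a list with elements `id`,
#'   `sequence` and `regions`.
#' @examples
#' a <- antigen("toy", "ACDEFGHIKLMNPQRSTVWY",
#'              regions(5, 12, "epitope"))
#' a
#' @export
antigen <- function(id, sequence, regions = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) < 1L)
    stop("antigen '", id, "': sequence must have length >= 1")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA20)
  if (length(bad))
    stop("antigen '", id, "': non-canonical residue(s): ",
         paste(bad, collapse = ", "))
  a <- structure(list(id = id, sequence = sequence,
                      regions = empty_regions()),
                 class = "antigen")
  if (!is.null(regions)) a <- set_regions(a, regions)
  a
}

empty_regions <- function() {
  data.frame(start = integer(), end = integer(),
             label = character(), score = numeric())
}

#' Build a region annotation table
#'
#' @param start,end 1-based inclusive coordinates (vectors recycle).
#' @param label One of `"epitope"`, `"nonepitope"`, `"reactive"`,
#'   `"predicted"`.
#' @param score Optional per-region score in \[0, 1\] (`NA` if absent).
#' @return Data frame with columns `start`, `end`, `label`, `score`.
#' @export
regions <- function(start, end, label, score = NA_real_) {
  r <- data.frame(start = as.integer(start), end = as.integer(end),
                  label = as.character(label), score = as.numeric(score))
  validate_regions(r)
  r
}

validate_regions <- function(r, L = NULL, antigen_id = "") {
  where <- if (nzchar(antigen_id)) paste0(" (antigen '", antigen_id, "')") else ""
  if (!all(c("start", "end", "label") %in% names(r)))
    stop("region table needs columns start, end, label", where)
  if (any(is.na(r$start)) || any(is.na(r$end)))
    stop("region coordinates must not be NA", where)
  if (any(r$start < 1L)) stop("region start < 1", where)
  if (any(r$start > r$end))
    stop("inverted region interval (start > end)", where)
  bad <- setdiff(unique(r$label), REGION_LABELS)
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "), where)
  if (!is.null(L) && any(r$end > L))
    stop("region end beyond sequence length ", L, where)
  if ("score" %in% names(r) &&
      any(!is.na(r$score) & (r$score < 0 | r$score > 1)))
    stop("region scores must lie in [0, 1]", where)
  invisible(r)
}

set_regions <- function(a, r) {
  if (is.null(r$score)) r$score <- NA_real_
  validate_regions(r, L = nchar(a$sequence), antigen_id = a$id)
  a$regions <- r[order(r$start, r$end), , drop = FALSE]
  rownames(a$regions) <- NULL
  a
}

#' @export
print.antigen <- function(x, ...) {
  cat("Antigen '", x$id, "': ", nchar(x$sequence), " aa\n", sep = "")
  if (nrow(x$regions)) {
    tab <- table(x$regions$label)
    cat("  regions:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  } else cat("  regions: none\n")
  invisible(x)
}

#' Per-residue class labels of an antigen
#'
#' Expands the interval annotations to one label per residue.  Residues
#' covered by an epitope region are `"epitope"` (epitope takes precedence
#' over nonepitope where annotations overlap), residues covered only by
#' nonepitope regions are `"nonepitope"`, and residues covered by neither
#' are `"unassigned"`.
#'
#' @param a An [antigen()].
#' @return Character vector of length `nchar(a$sequence)`.
#' @export
residue_labels <- function(a) {
  L <- nchar(a$sequence)
  lab <- rep("unassigned", L)
  r <- a$regions
  for (i in which(r$label == "nonepitope"))
    lab[r$start[i]:r$end[i]] <- "nonepitope"
  for (i in which(r$label == "epitope"))
    lab[r$start[i]:r$end[i]] <- "epitope"
  lab
}
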