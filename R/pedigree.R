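#' Pedigree records
#'
#' An ordered table of (id, sire, dam) triples.  Unknown parents are
#' stored as `NA`.  Records are topologically sorted so that every parent
#' precedes its offspring; parents that never appear as individuals are
#' appended as implicit founders.
#'
#' @param id character vector of unique individual ids.
#' @param sire,dam character vectors of parent ids; `NA`, `""`, `"0"` and
#'   `"NA"` all mean unknown.
#' @return an object of class `pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam`, topologically sorted.
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id)
  sire <- normalize_parent(sire)
  dam <- normalize_parent(dam)
  if (length(sire) != length(id) || length(dam) != length(id)) {
    stop("'id', 'sire' and 'dam' must have equal length")
  }
  dup <- id[duplicated(id)]
  if (length(dup) > 0L) {
    stop("duplicate individual ids: ", paste(unique(dup), collapse = ", "))
  }
  self <- id[!is.na(sire) & sire == id | !is.na(dam) & dam == id]
  if (length(self) > 0L) {
    stop("individual listed as its own parent (cycle): ",
         paste(self, collapse = ", "))
  }
  # append implicit founders for parents never listed as individuals
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents) > 0L) {
    id <- c(id, parents)
    sire <- c(sire, rep(NA_character_, length(parents)))
    dam <- c(dam, rep(NA_character_, length(parents)))
  }
  ord <- pedigree_toposort(id, sire, dam)
  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("", "0", "NA")] <- NA_character_
  x
}

# Kahn's algorithm; errors with the offending cycle if one exists.
pedigree_toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  par1 <- idx[sire]  # NA for unknown
  par2 <- idx[dam]
  indeg <- as.integer(!is.na(par1)) + as.integer(!is.na(par2))
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(par1[i], par2[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0L) {
    # stable: take the earliest-listed available individual
    i <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(id[setdiff(idx, ord)], collapse = ", "))
  }
  ord
}

#' Read a pedigree from a delimited text file
#'
#' Expects three columns (id, sire, dam); a header row is detected and
#' skipped if its first field is one of `id`, `ID`, `Id`.  Unknown parents
#' may be encoded as `0`, `NA` or an empty field.
#'
#' @param path file path.
#' @param delimiter field delimiter, default comma.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path, delimiter = ",") {
  df <- utils::read.table(path, header = FALSE, sep = delimiter,
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (ncol(df) < 3L) stop("pedigree file needs 3 columns: id, sire, dam")
  if (nrow(df) > 0L && tolower(df[1L, 1L]) %in% c("id")) {
    df <- df[-1L, , drop = FALSE]
  }
  pedigree(df[[1L]], df[[2L]], df[[3L]])
}

#' Write a pedigree to a delimited text file
#'
#' Unknown parents are written as `0`.
#'
#' @param ped a [pedigree()].
#' @param path output file path.
#' @param delimiter field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, delimiter = ",") {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Pedigree-based additive relationship matrix (tabular method)
#'
#' Standard diploid numerator relationship matrix by the recursive tabular
#' method: for individual `i` with parents `s`, `d` (processed in
#' pedigree order), `a(i,i) = 1 + 0.5 a(s,d)` and
#' `a(i,j) = 0.5 (a(j,s) + a(j,d))` for every earlier individual `j`;
#' unknown parents contribute 0 and founders are unrelated and
#' non-inbred.
#'
#' @param ped a [pedigree()] (already topologically sorted).
#' @return a [labeled_matrix()] over the pedigree ids.
#' @export
amatrix_tabular <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped$id, ped$sire, ped$dam)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  s <- idx[ped$sire]
  d <- idx[ped$dam]
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    asd <- if (!is.na(s[i]) && !is.na(d[i])) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rs <- if (!is.na(s[i])) A[j, s[i]] else 0
      rd <- if (!is.na(d[i])) A[j, d[i]] else 0
      aij <- 0.5 * (rs + rd)
      A[j, i] <- aij
      A[i, j] <- aij
    }
  }
  labeled_matrix(A, labels = ped$id, source = "amatrix_tabular")
}
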