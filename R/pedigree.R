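# Pedigree construction (half-diallel and maternal-only designs) and the
# additive (numerator) relationship matrix A by the tabular method.

#' Construct and validate a pedigree
#'
#' Records are (individual, sire, dam) with `NA` for unknown parents;
#' parents must precede their offspring (topological order), which also
#' rules out self-ancestry. Founders are assumed non-inbred and mutually
#' unrelated; unknown parents are treated as unique unrelated founders.
#'
#' @param id Character vector of unique individual ids.
#' @param sire,dam Parent ids (`NA` = unknown), same length as `id`.
#' @return data.frame of class `"sym_pedigree"` with columns id, sire, dam.
#' @export
pedigree <- function(id, sire = rep(NA_character_, length(id)),
                     dam = rep(NA_character_, length(id))) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  if (anyDuplicated(id))
    stop_symh2(sprintf("duplicate individual id: %s",
                       paste(unique(id[duplicated(id)]), collapse = ", ")))
  if (length(sire) != length(id) || length(dam) != length(id))
    stop_symh2("id, sire and dam must have equal length")
  seen <- character(0)
  for (i in seq_along(id)) {
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) {
        if (p == id[i]) stop_symh2(sprintf("%s listed as its own parent", id[i]))
        if (!p %in% seen)
          stop_symh2(sprintf("parent %s of %s not listed before its offspring",
                             p, id[i]))
      }
    }
    seen <- c(seen, id[i])
  }
  structure(data.frame(id = id, sire = sire, dam = dam,
                       stringsAsFactors = FALSE),
            class = c("sym_pedigree", "data.frame"))
}

#' Half-diallel pedigree from parents, crosses and offspring counts
#'
#' Builds the pedigree of a (half-)diallel breeding design: the listed
#' parents as founders, then the offspring of each gamete cross.
#' Self-crosses are rejected.
#'
#' @param parents Character vector of parent ids.
#' @param crosses Two-column matrix or data.frame of (sire, dam) ids.
#' @param offspring_counts Number of offspring per cross (recycled).
#' @return A [pedigree()] with founders first. Offspring ids are
#'   `"<sire>x<dam>_<k>"`.
#' @export
build_diallel_pedigree <- function(parents, crosses, offspring_counts = 1L) {
  crosses <- as.matrix(crosses)
  if (ncol(crosses) != 2L) stop_symh2("crosses must have two columns (sire, dam)")
  offspring_counts <- rep_len(as.integer(offspring_counts), nrow(crosses))
  unknown <- setdiff(c(crosses), parents)
  if (length(unknown))
    stop_symh2(sprintf("cross references unknown parent(s): %s",
                       paste(unknown, collapse = ", ")))
  if (any(crosses[, 1L] == crosses[, 2L]))
    stop_symh2("self-crosses are not allowed in a half-diallel design")
  ids <- as.character(parents); sires <- rep(NA_character_, length(parents))
  dams <- rep(NA_character_, length(parents))
  for (k in seq_len(nrow(crosses))) {
    nk <- offspring_counts[k]
    if (nk < 1L) next
    off <- sprintf("%sx%s_%d", crosses[k, 1L], crosses[k, 2L], seq_len(nk))
    ids <- c(ids, off)
    sires <- c(sires, rep(crosses[k, 1L], nk))
    dams <- c(dams, rep(crosses[k, 2L], nk))
  }
  pedigree(ids, sires, dams)
}

#' Maternal-only pedigree (dams and their eggs)
#'
#' Eggs are modeled as diploid offspring with a known dam and an unknown
#' sire, so eggs of one dam are maternal half-sibs (A = 0.25) under the
#' tabular rules.
#'
#' @param dams Character vector of dam ids.
#' @param eggs_per_dam Egg count per dam (recycled), each >= 1.
#' @return A [pedigree()] with dams first; egg ids `"<dam>_egg<k>"`.
#' @export
build_maternal_pedigree <- function(dams, eggs_per_dam) {
  eggs_per_dam <- rep_len(as.integer(eggs_per_dam), length(dams))
  if (any(eggs_per_dam < 1L)) stop_symh2("each dam must have at least one egg")
  ids <- as.character(dams); sires <- rep(NA_character_, length(dams))
  dmv <- rep(NA_character_, length(dams))
  for (k in seq_along(dams)) {
    off <- sprintf("%s_egg%d", dams[k], seq_len(eggs_per_dam[k]))
    ids <- c(ids, off)
    sires <- c(sires, rep(NA_character_, eggs_per_dam[k]))
    dmv <- c(dmv, rep(as.character(dams[k]), eggs_per_dam[k]))
  }
  pedigree(ids, sires, dmv)
}

#' Additive relationship matrix A (tabular method)
#'
#' Computes the numerator relationship matrix recursively over the
#' topologically ordered pedigree: for individual i with parents s, d,
#' `A[j, i] = 0.5 * (A[j, s] + A[j, d])` for earlier j (unknown parents
#' contribute 0) and `A[i, i] = 1 + 0.5 * A[s, d]` (0 if either parent is
#' unknown). Founders get diagonal 1; the result is symmetric positive
#' semi-definite.
#'
#' @param ped A [pedigree()].
#' @return Symmetric matrix with the pedigree's individual ids as dimnames.
#' @export
additive_relationship_matrix <- function(ped) {
  if (!inherits(ped, "sym_pedigree")) ped <- pedigree(ped$id, ped$sire, ped$dam)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  if (any(!is.na(si) & si >= seq_len(n)) || any(!is.na(di) & di >= seq_len(n)))
    stop_symh2("pedigree is not topologically ordered")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      contrib <- numeric(i - 1L)
      if (!is.na(s)) contrib <- contrib + A[j, s]
      if (!is.na(d)) contrib <- contrib + A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * contrib
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Read a pedigree from CSV
#'
#' Header `individual_id,sire_id,dam_id`; unknown parents encoded as an
#' empty field or `NA`.
#'
#' @param path Path to the pedigree CSV.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  need <- c("individual_id", "sire_id", "dam_id")
  if (!all(need %in% names(df)))
    stop_symh2("pedigree CSV must have columns individual_id,sire_id,dam_id")
  pedigree(df$individual_id, df$sire_id, df$dam_id)
}

#' Write a pedigree to CSV
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  df <- data.frame(individual_id = ped$id, sire_id = ped$sire,
                   dam_id = ped$dam, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
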