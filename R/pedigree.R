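#' Pedigree tables and the numerator relationship matrix
#'
#' A pedigree is a three-column data frame (`animal`, `sire`, `dam`) with one
#' row per animal; unknown parents are `NA`. Ids are arbitrary strings (or
#' anything coercible to character) mapped to dense integer indices
#' internally. Unknown parents are treated as unrelated, non-inbred founders;
#' no genetic-group structure is imposed.
#'
#' @name pedigree
NULL

#' Construct a pedigree table
#'
#' @param animal,sire,dam vectors of ids; `sire`/`dam` may contain `NA` (or
#'   `"0"`/`""`, which are converted to `NA`) for unknown parents.
#' @return A `data.frame` of class `pedigree_table` with character columns
#'   `animal`, `sire`, `dam`.
#' @export
pedigree_table <- function(animal, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  animal <- as.character(animal)
  if (anyDuplicated(animal)) {
    stop("duplicated animal ids: ", paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  ped <- data.frame(animal = animal, sire = norm(sire), dam = norm(dam),
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Read / write the 3-column pedigree TSV
#'
#' The on-disk format is tab-separated `animal  sire  dam` with a header row;
#' `0`, `NA` or an empty field mark an unknown parent. Reading back a written
#' file reproduces the table exactly.
#'
#' @param path file path.
#' @return `read_pedigree` returns a `pedigree_table`.
#' @export
read_pedigree <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", na.strings = c("NA", "0", ""))
  pedigree_table(x$animal, x$sire, x$dam)
}

#' @rdname read_pedigree
#' @param ped a `pedigree_table`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "NA"
  out$dam[is.na(out$dam)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Topologically sort a pedigree so parents precede offspring
#'
#' Stable Kahn sort: among animals whose parents are already placed, original
#' order is preserved, so an already-sorted pedigree passes through unchanged.
#'
#' @param ped a `pedigree_table`.
#' @return the sorted `pedigree_table`.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  if (n == 0L) return(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  absent <- c(ped$sire[!is.na(ped$sire) & is.na(si)],
              ped$dam[!is.na(ped$dam) & is.na(di)])
  if (length(absent)) {
    stop("parents not listed as animals in the pedigree: ",
         paste(unique(absent), collapse = ", "))
  }
  placed <- logical(n)
  order_out <- integer(n)
  k <- 0L
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) break
    w <- which(ready)
    order_out[k + seq_along(w)] <- w
    k <- k + length(w)
    placed[w] <- TRUE
  }
  if (k < n) {
    stop("pedigree contains a parentage cycle involving animal '",
         ped$animal[which(!placed)[1L]], "'")
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Integer-index view of a sorted pedigree: sire/dam as row indices (NA unknown).
ped_indices <- function(ped) {
  list(id = ped$animal,
       s = match(ped$sire, ped$animal),
       d = match(ped$dam, ped$animal))
}

#' Build the numerator relationship matrix A by the tabular method
#'
#' For a sorted pedigree, `a_jj = 1 + 0.5 * a(sire(j), dam(j))` and
#' `a_ij = 0.5 * (a(i, sire(j)) + a(i, dam(j)))` for `i < j`; missing parents
#' contribute 0. The diagonal is `1 + F` with `F` the inbreeding coefficient.
#'
#' @param ped a `pedigree_table` (sorted internally if needed).
#' @return list of class `relationship_matrix` with elements `A` (dense
#'   symmetric matrix with dimnames = animal ids), `F` (named inbreeding
#'   vector) and `ids`.
#' @export
build_A <- function(ped) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  pi_ <- ped_indices(ped)
  A <- matrix(0, n, n, dimnames = list(pi_$id, pi_$id))
  for (j in seq_len(n)) {
    s <- pi_$s[j]; d <- pi_$d[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      row <- numeric(j - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[i, s]
      if (!is.na(d)) row <- row + 0.5 * A[i, d]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  out <- list(A = A, F = stats::setNames(diag(A) - 1, pi_$id), ids = pi_$id)
  class(out) <- "relationship_matrix"
  out
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes `F` for every animal of a sorted pedigree in O(n * depth^2)
#' without forming A, together with the Mendelian-sampling variances
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (with the usual adjustments when a parent
#' is unknown) that Henderson's A-inverse rules need.
#'
#' @param ped a `pedigree_table`.
#' @return list with named vectors `F` and `d` in sorted-pedigree order,
#'   and the sorted pedigree as `pedigree`.
#' @export
inbreeding <- function(ped) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  pi_ <- ped_indices(ped)
  s <- pi_$s; d <- pi_$d
  Fv <- numeric(n)
  dv <- numeric(n)
  # L and D buffers for the recursion A = T L D L' T' (Meuwissen & Luo 1992)
  point <- integer(n); w <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    dv[i] <- 0.5 - 0.25 * ((if (is.na(si)) -1 else Fv[si]) +
                           (if (is.na(di)) -1 else Fv[di]))
    if (is.na(si) || is.na(di)) {
      Fv[i] <- 0
      next
    }
    if (si == di) {
      Fv[i] <- 0.5 * (1 + Fv[si])
      dv[i] <- 0.5 - 0.25 * (Fv[si] + Fv[di])
      next
    }
    # accumulate contributions of ancestors to a(si, di)
    fi <- 0
    active <- integer(0)
    w[si] <- w[si] + 0.5
    w[di] <- w[di] + 0.5
    active <- c(si, di)
    # process ancestors from youngest to oldest
    heap <- sort(unique(active), decreasing = TRUE)
    seen <- unique(active)
    while (length(heap)) {
      j <- heap[1L]; heap <- heap[-1L]
      wj <- w[j]
      if (wj == 0) next
      fi <- fi + wj * wj * dv[j]
      for (p in c(s[j], d[j])) {
        if (!is.na(p)) {
          if (w[p] == 0 && !(p %in% heap)) {
            heap <- sort(c(heap, p), decreasing = TRUE)
            seen <- c(seen, p)
          }
          w[p] <- w[p] + 0.5 * wj
        }
      }
      w[j] <- 0
    }
    w[seen] <- 0
    # with w initialised at 0.5 on each parent, fi = sum w_j^2 d_j equals
    # 0.25*a_ss + 0.25*a_dd + 0.5*a_sd; F_i = 0.5*a_sd:
    Fv[i] <- fi - 0.5 - 0.25 * (Fv[si] + Fv[di])
    dv[i] <- 0.5 - 0.25 * (Fv[si] + Fv[di])
  }
  list(F = stats::setNames(Fv, pi_$id), d = stats::setNames(dv, pi_$id),
       pedigree = ped)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: with Mendelian-sampling
#' variance `d_i` (from [inbreeding()]), `alpha_i = 1/d_i` is added to the
#' (i,i) cell, `-alpha_i/2` to animal-parent cells and `alpha_i/4` among
#' parents. The result is sparse: nonzeros connect an animal, its parents and
#' its mates only.
#'
#' @param ped a `pedigree_table`.
#' @return list of class `relationship_inverse` with `Ainv` (a
#'   `Matrix::dsCMatrix`), `F`, `d`, `log_det_A` (`= sum(log d_i)`) and `ids`.
#' @export
build_A_inverse <- function(ped) {
  ib <- inbreeding(ped)
  ped <- ib$pedigree
  n <- nrow(ped)
  pi_ <- ped_indices(ped)
  s <- pi_$s; d <- pi_$d
  alpha <- 1 / ib$d
  # vectorised triplet assembly
  anim <- seq_len(n)
  trip_i <- anim; trip_j <- anim; trip_x <- alpha
  hs <- !is.na(s); hd <- !is.na(d)
  trip_i <- c(trip_i, anim[hs], s[hs], anim[hd], d[hd])
  trip_j <- c(trip_j, s[hs], anim[hs], d[hd], anim[hd])
  trip_x <- c(trip_x, rep(-alpha[hs] / 2, 2), rep(-alpha[hd] / 2, 2))
  trip_i <- c(trip_i, s[hs], d[hd])
  trip_j <- c(trip_j, s[hs], d[hd])
  trip_x <- c(trip_x, alpha[hs] / 4, alpha[hd] / 4)
  both <- hs & hd
  trip_i <- c(trip_i, s[both], d[both])
  trip_j <- c(trip_j, d[both], s[both])
  trip_x <- c(trip_x, rep(alpha[both] / 4, 2))
  Ainv <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                               dims = c(n, n), dimnames = list(pi_$id, pi_$id),
                               symmetric = FALSE)
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  out <- list(Ainv = Ainv, F = ib$F, d = ib$d,
              log_det_A = sum(log(ib$d)), ids = pi_$id)
  class(out) <- "relationship_inverse"
  out
}

#' Write a relationship matrix (or its inverse) in coordinate format
#'
#' Emits `i  j  value` triples (1-based indices, upper triangle included
#' once) plus a companion id-map file `<path>.ids` with `index  id`.
#'
#' @param x a `relationship_matrix` or `relationship_inverse`.
#' @param path output path.
#' @export
write_relationship_coo <- function(x, path) {
  if (inherits(x, "relationship_matrix")) {
    M <- x$A
    idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1], j = idx[, 2], value = M[idx])
  } else {
    M <- Matrix::triu(x$Ainv)
    tm <- methods::as(M, "TsparseMatrix")
    df <- data.frame(i = tm@i + 1L, j = tm@j + 1L, value = tm@x)
    df <- df[order(df$i, df$j), ]
  }
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(index = seq_along(x$ids), id = x$ids),
                     paste0(path, ".ids"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
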