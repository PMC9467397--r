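#' Kinship matrix by the recursive tabular method
#'
#' Computes the kinship coefficient phi for every pair of pedigree members.
#' Individuals are processed in an order that puts parents before children;
#' for a non-founder i with parents f and m and any earlier-processed j,
#' phi(i, j) = (phi(f, j) + phi(m, j)) / 2 (an unknown parent contributes 0),
#' and phi(i, i) = (1 + phi(f, m)) / 2, so inbreeding is handled. Founders
#' are assumed unrelated and non-inbred: phi = 0.5 on the diagonal, 0
#' between founders. 2 * phi is the expected proportion of genes shared
#' (the additive relationship): 0.5 for full siblings and parent-child,
#' 0.25 for half-siblings and avuncular pairs.
#'
#' @param ped a [pedigree].
#' @return Symmetric numeric matrix of kinship coefficients with
#'   individual ids as dimnames, rows/columns in pedigree order.
#' @export
compute_kinship <- function(ped) {
  stopifnot(is_pedigree(ped))
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  if (n == 0) return(phi)
  ord <- attr(ped, "topo_order")
  if (is.null(ord)) ord <- topological_order(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  for (k in seq_len(n)) {
    i <- ord[k]
    f <- fa[i]; m <- mo[i]
    if (k > 1) {
      prev <- ord[seq_len(k - 1)]
      row_f <- if (is.na(f)) 0 else phi[f, prev]
      row_m <- if (is.na(m)) 0 else phi[m, prev]
      v <- (row_f + row_m) / 2
      phi[i, prev] <- v
      phi[prev, i] <- v
    }
    phi_fm <- if (is.na(f) || is.na(m)) 0 else phi[f, m]
    phi[i, i] <- (1 + phi_fm) / 2
  }
  phi
}

#' Additive relationship matrix restricted to phenotyped members
#'
#' Kinship is computed over the full pedigree (so indirect relationships
#' through unphenotyped connectors are correct) and the 2*phi sub-matrix for
#' the phenotyped individuals is extracted for model fitting.
#'
#' @param ped a [pedigree].
#' @param ids optional character vector selecting/ordering individuals;
#'   default: phenotyped members in pedigree order.
#' @return 2*Phi matrix over the selected individuals.
#' @export
relationship_matrix <- function(ped, ids = NULL) {
  if (is.null(ids)) ids <- ped$id[ped$phenotyped]
  miss <- setdiff(ids, ped$id)
  if (length(miss) > 0)
    stop("ids not in pedigree: ", paste(miss, collapse = ", "))
  2 * compute_kinship(ped)[ids, ids, drop = FALSE]
}

#' Export a kinship matrix as CSV
#'
#' Writes the matrix with a header row and a leading id column.
#'
#' @param phi kinship (or relationship) matrix with dimnames.
#' @param path output path.
#' @export
write_kinship_csv <- function(phi, path) {
  df <- data.frame(id = rownames(phi), phi, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify within-family relative pairs structurally
#'
#' Labels every within-family pair of members by pedigree structure, not by
#' the kinship value (parent-child and full siblings both have phi = 0.25):
#' \describe{
#'   \item{parent-child}{one is a listed parent of the other}
#'   \item{full-sibling}{both listed parents shared}
#'   \item{half-sibling}{exactly one shared listed parent}
#'   \item{avuncular}{one is a full sibling of a listed parent of the other}
#'   \item{other}{any remaining pair with kinship > 0}
#'   \item{unrelated}{within-family pair with kinship 0 (e.g. spouses)}
#' }
#'
#' @param ped a [pedigree].
#' @param phenotyped_only restrict to phenotyped members (the study sample).
#' @return A data frame with columns `id1`, `id2`, `fid`, `label`,
#'   `expected_sharing` (2*phi), plus a `census` attribute: a named count of
#'   the labels. Empty pedigree gives zero rows.
#' @export
classify_relative_pairs <- function(ped, phenotyped_only = TRUE) {
  stopifnot(is_pedigree(ped))
  phi <- compute_kinship(ped)
  keep <- if (phenotyped_only) ped$phenotyped else rep(TRUE, nrow(ped))
  empty <- data.frame(id1 = character(0), id2 = character(0),
                      fid = character(0), label = character(0),
                      expected_sharing = numeric(0))
  members <- ped[keep, , drop = FALSE]
  rows <- list()
  full_sibs <- function(a, b) {
    !is.na(ped$father[a]) && !is.na(ped$mother[a]) &&
      identical(ped$father[a], ped$father[b]) &&
      identical(ped$mother[a], ped$mother[b])
  }
  idx <- match(members$id, ped$id)
  for (f in unique(members$fid)) {
    fam <- idx[members$fid == f]
    if (length(fam) < 2) next
    cmb <- utils::combn(fam, 2)
    for (c in seq_len(ncol(cmb))) {
      a <- cmb[1, c]; b <- cmb[2, c]
      ida <- ped$id[a]; idb <- ped$id[b]
      shared <- sum(stats::na.omit(c(ped$father[a], ped$mother[a])) %in%
                    stats::na.omit(c(ped$father[b], ped$mother[b])))
      is_pc <- identical(ped$father[b], ida) || identical(ped$mother[b], ida) ||
               identical(ped$father[a], idb) || identical(ped$mother[a], idb)
      avunc <- function(x, y) {
        # x full sibling of a listed parent of y
        pars <- match(stats::na.omit(c(ped$father[y], ped$mother[y])), ped$id)
        any(vapply(pars, function(p) full_sibs(x, p), logical(1)))
      }
      label <-
        if (is_pc) "parent-child"
        else if (full_sibs(a, b)) "full-sibling"
        else if (shared == 1) "half-sibling"
        else if (avunc(a, b) || avunc(b, a)) "avuncular"
        else if (phi[a, b] > 0) "other"
        else "unrelated"
      rows[[length(rows) + 1]] <- data.frame(
        id1 = ida, id2 = idb, fid = f, label = label,
        expected_sharing = 2 * phi[a, b], stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) == 0) empty else do.call(rbind, rows)
  lv <- c("parent-child", "full-sibling", "half-sibling", "avuncular",
          "other", "unrelated")
  attr(out, "census") <- table(factor(out$label, levels = lv))
  out
}

#' Relationship label of one pair
#'
#' Convenience wrapper around [classify_relative_pairs()] for a single pair;
#' pairs in different families are `"unrelated"`.
#'
#' @param ped a [pedigree].
#' @param id1,id2 individual ids.
#' @return Character label.
#' @export
relationship_label <- function(ped, id1, id2) {
  stopifnot(is_pedigree(ped), id1 %in% ped$id, id2 %in% ped$id)
  if (ped$fid[ped$id == id1] != ped$fid[ped$id == id2]) return("unrelated")
  pairs <- classify_relative_pairs(ped, phenotyped_only = FALSE)
  hit <- (pairs$id1 == id1 & pairs$id2 == id2) |
         (pairs$id1 == id2 & pairs$id2 == id1)
  pairs$label[hit]
}

#' Relative-pair census
#'
#' @param ped a [pedigree].
#' @param phenotyped_only restrict to phenotyped members.
#' @return Named table of within-family pair counts by relationship label.
#' @export
pair_census <- function(ped, phenotyped_only = TRUE) {
  attr(classify_relative_pairs(ped, phenotyped_only), "census")
}
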