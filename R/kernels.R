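# Jaccard/Tanimoto similarity between rows of binary matrices X and Y.
# Identical empty sets are assigned similarity 1 (identical-sets convention).
binary_similarity <- function(X, Y = NULL, method = c("jaccard", "gaussian"),
                              sigma = NULL) {
  method <- match.arg(method)
  if (is.null(Y)) Y <- X
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (method == "jaccard") {
    inter <- tcrossprod(X, Y)
    uni <- outer(rowSums(X), rowSums(Y), "+") - inter
    K <- ifelse(uni == 0, 1, inter / uni)
  } else {
    # Gaussian on binary vectors: exp(-||x - y||^2 / (2 sigma^2))
    if (is.null(sigma)) sigma <- sqrt(ncol(X)) / 2
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    K <- exp(-pmax(d2, 0) / (2 * sigma^2))
  }
  dimnames(K) <- list(rownames(X), rownames(Y))
  K
}

#' Genomic kernel between mutation profiles
#'
#' Similarity matrix over samples from binary mutation profiles. The
#' default is the Jaccard similarity of mutated-gene sets
#' (`|intersection| / |union|`), which is bounded in `[0, 1]`, has unit
#' diagonal and is positive semidefinite. Two all-zero profiles get
#' similarity 1 (identical sets). A Gaussian-on-binary alternative is
#' available behind the same interface.
#'
#' @param profiles Binary samples x genes matrix (rownames = sample ids).
#' @param anchors Optional second profile matrix on the same panel; when
#'   given, the rectangular cross-similarity `profiles x anchors` is
#'   returned (used to project new patients onto training anchors).
#' @param method `"jaccard"` (default) or `"gaussian"`.
#' @param sigma Bandwidth for the Gaussian variant.
#' @return Similarity matrix with entries in `[0, 1]`.
#' @examples
#' m <- rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1))
#' genomic_kernel(m)["s1", "s2"]  # |{1,2} ∩ {2,3}| / |{1,2} ∪ {2,3}| = 1/3
#' @export
genomic_kernel <- function(profiles, anchors = NULL,
                           method = c("jaccard", "gaussian"), sigma = NULL) {
  if (nrow(profiles) < 2L && is.null(anchors)) {
    stop("need at least 2 profiles", call. = FALSE)
  }
  if (!is.null(anchors) && !identical(colnames(profiles), colnames(anchors))) {
    stop("gene panels differ between `profiles` and `anchors`", call. = FALSE)
  }
  binary_similarity(profiles, anchors, match.arg(method), sigma)
}

#' Chemical kernel between drug fingerprints
#'
#' Tanimoto coefficient between fingerprint bit-vectors (identical to the
#' Jaccard similarity of their set-bit sets), the standard 2D chemical
#' similarity. All-zero fingerprint pairs get similarity 1 by the
#' identical-sets convention.
#'
#' @param fingerprints Binary drugs x bits matrix (rownames = drug ids).
#' @param anchors Optional second fingerprint matrix of the same length;
#'   returns the rectangular cross-similarity when given.
#' @param method `"jaccard"` (Tanimoto, default) or `"gaussian"`.
#' @param sigma Bandwidth for the Gaussian variant.
#' @return Similarity matrix with entries in `[0, 1]`.
#' @examples
#' fp <- rbind(d1 = c(1, 1, 0), d2 = c(0, 1, 1))
#' chemical_kernel(fp)["d1", "d2"]  # 1/3
#' @export
chemical_kernel <- function(fingerprints, anchors = NULL,
                            method = c("jaccard", "gaussian"), sigma = NULL) {
  if (!is.null(anchors) && ncol(fingerprints) != ncol(anchors)) {
    stop("fingerprint lengths differ", call. = FALSE)
  }
  binary_similarity(fingerprints, anchors, match.arg(method), sigma)
}

# Check the KernelMatrix contract: symmetry, unit diagonal, PSD.
check_kernel <- function(K, tol_sym = 1e-12, tol_psd = -1e-8) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > tol_sym) stop("kernel not symmetric", call. = FALSE)
  if (max(abs(diag(K) - 1)) > 1e-12) stop("kernel diagonal not 1", call. = FALSE)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < tol_psd) {
    stop(sprintf("kernel not PSD (min eigenvalue %.3g)", min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Anchor-similarity feature vectors for (cell, drug) pairs
#'
#' Represents each pair by the concatenation of the cell's genomic-kernel
#' row restricted to the anchor cells and the drug's chemical-kernel row
#' restricted to the anchor drugs, in anchor order. New patients enter only
#' through their kernel rows against the training anchors, so prediction
#' needs no refit.
#'
#' @param cell_ids,drug_ids Character vectors of equal length naming each
#'   pair.
#' @param Kg Genomic similarity matrix with `cell_ids` among its rownames
#'   and the anchor cells among its colnames.
#' @param Kc Chemical similarity matrix with `drug_ids` among its rownames
#'   and the anchor drugs among its colnames.
#' @param anchor_cells,anchor_drugs Anchor id vectors; default all columns
#'   of `Kg` / `Kc`.
#' @return Numeric matrix, pairs x (anchor cells + anchor drugs), rownames
#'   `cell:drug`, with attributes `anchor_cells` and `anchor_drugs`.
#' @export
pair_features <- function(cell_ids, drug_ids, Kg, Kc,
                          anchor_cells = colnames(Kg),
                          anchor_drugs = colnames(Kc)) {
  stopifnot(length(cell_ids) == length(drug_ids))
  miss <- setdiff(unique(cell_ids), rownames(Kg))
  if (length(miss)) stop(sprintf("unknown cell id(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  miss <- setdiff(unique(drug_ids), rownames(Kc))
  if (length(miss)) stop(sprintf("unknown drug id(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  miss <- setdiff(anchor_cells, colnames(Kg))
  if (length(miss)) stop(sprintf("unknown anchor cell(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  miss <- setdiff(anchor_drugs, colnames(Kc))
  if (length(miss)) stop(sprintf("unknown anchor drug(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  X <- cbind(Kg[cell_ids, anchor_cells, drop = FALSE],
             Kc[drug_ids, anchor_drugs, drop = FALSE])
  colnames(X) <- c(paste0("cell.", anchor_cells), paste0("drug.", anchor_drugs))
  rownames(X) <- paste(cell_ids, drug_ids, sep = ":")
  attr(X, "anchor_cells") <- anchor_cells
  attr(X, "anchor_drugs") <- anchor_drugs
  X
}
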