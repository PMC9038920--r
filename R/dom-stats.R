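# Sample comparison: Bray-Curtis dissimilarity, principal coordinates
# analysis, and biogeochemical habitat classification.

#' Habitat category levels
#'
#' The five biogeochemical categories used to group samples: water-column
#' surface, oxycline and oxygen minimum zone (OMZ), and sediment core top
#' and subseafloor.
#'
#' @format Character vector of length 5.
#' @export
HABITATS <- c("surface", "oxycline", "OMZ", "core_top", "subseafloor")

.brayCurtisMatrix <- function(x, percent = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (any(x < 0)) stop("relative intensities must be non-negative")
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("undefined dissimilarity: sample(s) with all-zero intensities: ",
         paste(rownames(x)[rs == 0], collapse = ", "))
  # BC(j,k) = sum |x_j - x_k| / sum (x_j + x_k)
  d <- as.matrix(stats::dist(x, method = "manhattan")) /
    outer(rs, rs, "+")
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  if (percent) d * 100 else d
}

#' @rdname brayCurtis
#' @param percent report dissimilarities on the 0-100 scale instead of 0-1.
#' @export
setMethod("brayCurtis", "matrix",
          function(x, percent = FALSE) .brayCurtisMatrix(x, percent))

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", "DomSet",
          function(x, percent = FALSE)
            .brayCurtisMatrix(relIntensityMatrix(x), percent))

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: the squared
#' dissimilarities are double-centered (Gower), `B = -1/2 J D^2 J` with
#' `J = I - 11'/n`, and eigendecomposed.  Coordinates are returned for
#' positive eigenvalues only; negative eigenvalues (non-Euclidean input)
#' are reported but yield no axes, and no Lingoes/Cailliez correction is
#' applied.
#'
#' @param d symmetric dissimilarity `matrix` (zero diagonal) or [stats::dist].
#' @param eigTol relative tolerance below which an eigenvalue is treated as
#'   zero, default `1e-9` of the largest magnitude.
#' @return List with `coordinates` (samples x axes, axes ordered by
#'   decreasing eigenvalue), `eigenvalues` (all, sorted decreasing), and
#'   `proportionExplained` (over positive eigenvalues).
#' @examples
#' x <- matrix(c(1, 0, 0.5, 0.5, 0, 1), 3, 2, byrow = TRUE)
#' ord <- principalCoordinates(brayCurtis(x / rowSums(x)))
#' ord$proportionExplained
#' @export
principalCoordinates <- function(d, eigTol = 1e-9) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam <- e$values
  scale <- max(abs(lam), 0)
  pos <- which(lam > eigTol * max(scale, .Machine$double.eps))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lam[pos]), nrow = length(pos))
  rownames(coords) <- rownames(d)
  if (length(pos))
    colnames(coords) <- paste0("Axis", seq_along(pos))
  list(coordinates = coords,
       eigenvalues = lam,
       proportionExplained = if (length(pos)) lam[pos] / sum(lam[pos])
                             else numeric())
}

#' Assign a sample to a biogeochemical habitat category
#'
#' Water-column samples are classified by depth range — surface ocean
#' (5-10 m, 160-110 uM O2), oxycline (50-95 m, 110-40 uM O2), and OMZ
#' (95-125 m, < 60 uM O2) — with depth taking precedence where the stated
#' ranges meet (95 m is assigned to the OMZ).  Sediment samples are
#' classified by redox state: suboxic core-top versus sulfidic subseafloor
#' (12-28 cm below seafloor).  Metadata outside all stated ranges raise an
#' error rather than being silently binned.
#'
#' @param depth water depth in m, or sediment depth in cm below seafloor
#'   (vectorized).
#' @param o2 dissolved oxygen, uM; required for water samples.
#' @param matrixType `"water"` or `"sediment"`.
#' @param redox sediment redox state, `"suboxic"` or `"sulfidic"`.
#' @return Factor with levels [HABITATS].
#' @examples
#' assignHabitat(5, o2 = 150, matrixType = "water")           # surface
#' assignHabitat(23, matrixType = "sediment", redox = "sulfidic")
#' @export
assignHabitat <- function(depth, o2 = NA_real_,
                          matrixType = c("water", "sediment"),
                          redox = c("none", "suboxic", "sulfidic")) {
  matrixType <- match.arg(matrixType)
  redox <- match.arg(redox)
  one <- function(depth, o2) {
    if (matrixType == "water") {
      if (is.na(o2))
        stop("water samples require a dissolved O2 concentration")
      if (depth >= 5 && depth <= 10) return("surface")
      if (depth >= 50 && depth < 95) return("oxycline")
      if (depth >= 95 && depth <= 125) return("OMZ")
      stop(sprintf(
        "unclassifiable water sample: depth %.1f m outside all ranges",
        depth))
    }
    if (redox == "suboxic") return("core_top")
    if (redox == "sulfidic") {
      if (depth < 0 || depth > 30)
        stop(sprintf(
          "unclassifiable sediment sample: %.1f cmbsf outside core", depth))
      return("subseafloor")
    }
    stop("unclassifiable sediment sample: redox state required")
  }
  out <- mapply(one, depth, rep_len(o2, length(depth)))
  factor(out, levels = HABITATS)
}
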