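#' Phi association coefficient of two binary vectors
#'
#' With the 2x2 co-presence table a = both 1, b = x only, c = y only,
#' d = both 0, phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)). This is
#' exactly the Pearson correlation of the two 0/1 vectors. The value is
#' undefined (returned as `NA`) when either vector is constant.
#'
#' @param x,y binary (0/1) vectors of equal length >= 2.
#' @return a number in \[-1, 1\], or `NA_real_` when undefined.
#' @examples
#' phi_coefficient(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 0))  # 1/6
#' @export
phi_coefficient <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 2L) stop("vectors must have length >= 2", call. = FALSE)
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("x and y must be binary (0/1)", call. = FALSE)
  }
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  denom <- as.numeric(a + b) * (cc + d) * (a + cc) * (b + d)
  if (denom == 0) return(NA_real_)
  (as.numeric(a) * d - as.numeric(b) * cc) / sqrt(denom)
}

#' Phi-coefficient distance matrix over sample patterns
#'
#' Computes the pairwise phi coefficient between all sample rows of a
#' binary presence matrix and maps it to a distance. The default
#' transform d = (1 - phi)/2 bounds distances in \[0, 1\]: identical
#' non-constant patterns are at distance 0, complementary patterns at
#' 1. Both transforms are affine in phi, so any rank-based downstream
#' statistic is identical under either.
#'
#' Constant rows (all-zero or all-one patterns, e.g. sterile-looking
#' meconium samples) make phi undefined. Under the default
#' `constant_policy = "neutral"` such pairs get phi = 0 (d = 0.5 under
#' the default transform) unless the two rows are identical, in which
#' case d = 0; `"error"` aborts instead. Degenerate rows are reported
#' via a message.
#'
#' @param m binary presence matrix (samples x genera), >= 2 rows and
#'   >= 2 genus columns.
#' @param transform `"half_one_minus_phi"` (default, d = (1-phi)/2) or
#'   `"one_minus_phi"` (d = 1-phi, range \[0, 2\]).
#' @param constant_policy `"neutral"` (default) or `"error"`.
#' @return symmetric numeric matrix with zero diagonal and the sample
#'   ids as dimnames; the number of constant rows is attached as
#'   attribute `"constant_rows"`.
#' @export
phi_distance_matrix <- function(m,
                                transform = c("half_one_minus_phi",
                                              "one_minus_phi"),
                                constant_policy = c("neutral", "error")) {
  transform <- match.arg(transform)
  constant_policy <- match.arg(constant_policy)
  if (!is.matrix(m)) m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (ncol(m) < 2L) stop("need >= 2 genus columns", call. = FALSE)
  if (!all(m %in% c(0, 1))) stop("matrix must be binary (0/1)", call. = FALSE)
  storage.mode(m) <- "double"
  n <- nrow(m)
  g <- ncol(m)
  rs <- rowSums(m)
  a <- tcrossprod(m)                       # co-presence counts
  b <- matrix(rs, n, n) - a                # present in i only
  cc <- t(b)                               # present in j only
  d <- g - a - b - cc
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  phi <- matrix(NA_real_, n, n)
  ok <- denom > 0
  phi[ok] <- (a[ok] * d[ok] - b[ok] * cc[ok]) / sqrt(denom[ok])

  const <- rs == 0 | rs == g
  if (any(const)) {
    if (constant_policy == "error") {
      stop("constant (all-0 or all-1) pattern row(s): ",
           paste(rownames(m)[const], collapse = ", "), call. = FALSE)
    }
    message(sum(const), " constant pattern row(s); undefined phi set to 0",
            " (identical pairs to distance 0)")
    und <- which(is.na(phi), arr.ind = TRUE)
    if (nrow(und)) {
      same <- a[und] + d[und] == g          # identical patterns
      phi[und] <- ifelse(same, 1, 0)
    }
  }
  dist <- switch(transform,
                 half_one_minus_phi = (1 - phi) / 2,
                 one_minus_phi = 1 - phi)
  dist <- (dist + t(dist)) / 2
  diag(dist) <- 0
  dimnames(dist) <- list(rownames(m), rownames(m))
  attr(dist, "constant_rows") <- sum(const)
  attr(dist, "transform") <- transform
  dist
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(d))) {
    stop("distance matrix contains non-finite entries", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  if (is.null(rownames(d))) {
    stop("distance matrix must carry sample labels as dimnames",
         call. = FALSE)
  }
  invisible(d)
}

#' Write a distance matrix as CSV (header row + label column)
#'
#' @param d labelled symmetric distance matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  validate_distance_matrix(d)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
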