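#' Enumerate all attribute patterns
#'
#' Generates the complete latent space of binary attribute profiles for `K`
#' attributes. The ordering is canonical throughout the package: binary
#' counting with attribute 1 as the most significant bit, so for `K = 2` the
#' rows are (0,0), (0,1), (1,0), (1,1). Every posterior matrix, latent
#' distribution and item success-probability table indexes its `2^K` columns
#' (or rows) in this order.
#'
#' @param K Number of attributes (positive integer).
#' @return An `2^K x K` integer matrix; row `l` is attribute profile
#'   \eqn{\alpha_l}.
#' @examples
#' attributePatterns(2)
#' @export
attributePatterns <- function(K) {
  if (length(K) != 1L || is.na(K) || K < 1 || K != round(K))
    stop("'K' must be a positive integer", call. = FALSE)
  K <- as.integer(K)
  L <- 2L^K
  m <- matrix(0L, L, K)
  for (k in seq_len(K)) {
    # attribute k toggles every 2^(K-k) rows; attribute 1 is the slowest bit
    m[, k] <- rep(rep(c(0L, 1L), each = 2L^(K - k)), length.out = L)
  }
  colnames(m) <- paste0("A", seq_len(K))
  m
}

#' Index of an attribute profile in the canonical pattern order
#'
#' @param alpha Binary vector of length `K`.
#' @return 1-based row index of `alpha` in [attributePatterns()].
#' @export
patternIndex <- function(alpha) {
  K <- length(alpha)
  as.integer(sum(alpha * 2^(K - seq_len(K))) + 1)
}

#' Reduce a profile to the attributes an item requires
#'
#' An item only distinguishes latent classes through the attributes with
#' Q-matrix entries of 1; the reduced profile \eqn{\alpha^*_{lj}} is the
#' sub-vector of the full profile restricted to those attributes. The index
#' uses the same canonical (binary-counting) order on the reduced space.
#'
#' @param alpha Full binary attribute profile.
#' @param qrow Binary Q-matrix row for the item (same length as `alpha`).
#' @return 1-based index into the item's `2^{K*_j}` reduced-profile space.
#' @examples
#' reducedPatternIndex(c(1, 0, 1), c(1, 0, 1)) # reduced (1,1) -> index 4
#' @export
reducedPatternIndex <- function(alpha, qrow) {
  if (length(alpha) != length(qrow))
    stop("'alpha' and 'qrow' must have the same length", call. = FALSE)
  patternIndex(alpha[qrow == 1])
}

#' Per-item latent group index table
#'
#' Maps every full attribute profile to the item's latent response group.
#' Under the saturated (G-DINA) parameterization each of the `2^{K*_j}`
#' reduced profiles is its own group; under DINA there are only two groups
#' (1 = at least one required attribute lacking, 2 = all required attributes
#' mastered).
#'
#' @param Q A validated J x K Q-matrix.
#' @param model `"DINA"` or `"GDINA"`.
#' @return List with `index` (J x L integer matrix of 1-based group indices)
#'   and `ngroup` (integer J-vector of group counts per item).
#' @keywords internal
itemGroupIndex <- function(Q, model = c("GDINA", "DINA")) {
  model <- match.arg(model)
  K <- ncol(Q)
  J <- nrow(Q)
  pat <- attributePatterns(K)
  L <- nrow(pat)
  idx <- matrix(1L, J, L)
  ngroup <- integer(J)
  for (j in seq_len(J)) {
    req <- which(Q[j, ] == 1)
    if (model == "GDINA") {
      Ks <- length(req)
      w <- 2^(Ks - seq_len(Ks))
      idx[j, ] <- as.integer(pat[, req, drop = FALSE] %*% w + 1)
      ngroup[j] <- 2L^Ks
    } else {
      eta <- as.integer(rowSums(pat[, req, drop = FALSE]) == length(req))
      idx[j, ] <- eta + 1L
      ngroup[j] <- 2L
    }
  }
  list(index = idx, ngroup = ngroup)
}

#' Validate a Q-matrix
#'
#' Checks the structural requirements of a cognitive-diagnosis Q-matrix:
#' binary entries, every item requiring at least one attribute, and every
#' attribute required by at least one item.
#'
#' @param Q Matrix or data frame of 0/1 entries, items as rows.
#' @return The validated Q-matrix as an integer matrix.
#' @export
qMatrix <- function(Q) {
  Q <- as.matrix(Q)
  if (!all(Q %in% c(0, 1)))
    stop("Q-matrix entries must all be 0 or 1", call. = FALSE)
  storage.mode(Q) <- "integer"
  if (any(rowSums(Q) == 0))
    stop("Q-matrix row(s) ", paste(which(rowSums(Q) == 0), collapse = ", "),
         " require no attribute", call. = FALSE)
  if (any(colSums(Q) == 0))
    stop("Q-matrix column(s) ", paste(which(colSums(Q) == 0), collapse = ", "),
         " are required by no item", call. = FALSE)
  if (is.null(rownames(Q))) rownames(Q) <- paste0("Item", seq_len(nrow(Q)))
  if (is.null(colnames(Q))) colnames(Q) <- paste0("A", seq_len(ncol(Q)))
  Q
}

#' Built-in simulation Q-matrices (K = 5)
#'
#' The 30-item, five-attribute Q-matrix used throughout the simulation
#' harness: five one-attribute, ten two-attribute and ten three-attribute
#' items at `J = 30`. The `J = 15` version is the balanced subset (five items
#' of each complexity, every attribute required exactly six times).
#'
#' @param J Test length, 15 or 30.
#' @return A validated `J x 5` Q-matrix.
#' @examples
#' colSums(simQmatrix(15)) # every attribute measured 6 times
#' @export
simQmatrix <- function(J = c(30, 15)) {
  J <- match.arg(as.character(J[1]), c("30", "15"))
  rows <- c(
    "10000", "01000", "00100", "00010", "00001",
    "10000", "01000", "00100", "00010", "00001",
    "11000", "10100", "10010", "10001", "01100",
    "01010", "01001", "00110", "00101", "00011",
    "11100", "11010", "11001", "10110", "10101",
    "10011", "01110", "01101", "01011", "00111")
  sub15 <- c(6, 7, 8, 9, 10, 11, 14, 15, 18, 20, 21, 23, 26, 27, 30)
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  rownames(m) <- paste0("Item", seq_len(30))
  if (J == "15") m <- m[sub15, , drop = FALSE]
  qMatrix(m)
}

#' Q-matrix of the ECPE grammar section
#'
#' The 28-item, three-attribute expert Q-matrix for the grammar section of
#' the Examination for the Certificate of Proficiency in English
#' (morphosyntactic, cohesive and lexical rules). Provided for analyses of
#' the ECPE response data, which must be obtained separately.
#'
#' @return A validated `28 x 3` Q-matrix.
#' @export
ecpeQmatrix <- function() {
  rows <- c(
    "110", "010", "101", "001", "001", "001", "101", "010", "001", "100",
    "101", "101", "100", "100", "001", "101", "011", "001", "001", "101",
    "101", "001", "010", "010", "100", "001", "100", "001")
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  rownames(m) <- paste0("Item", seq_len(28))
  colnames(m) <- c("Morphosyntactic", "Cohesive", "Lexical")
  qMatrix(m)
}
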