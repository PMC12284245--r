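# FastICA (symmetric orthogonalization, tanh contrast) with deterministic
# seeded initialization, and EOG-correlation-based component rejection.

#' FastICA decomposition
#'
#' Whitens the data by PCA and estimates an orthogonal unmixing matrix by
#' fixed-point iteration with the tanh non-linearity and symmetric
#' decorrelation. Initialization is a seeded random orthogonal matrix, so
#' results are reproducible.
#'
#' @param x channels x samples matrix
#' @param n_comp number of components (default: numerical rank, at most
#'   the channel count)
#' @param seed integer seed for the initial unmixing matrix
#' @param max_iter,tol fixed-point iteration controls
#' @return list with `sources` (components x samples), `mixing`
#'   (channels x components), `unmixing`, `converged`, `iterations`
#' @export
fast_ica <- function(x, n_comp = NULL, seed = 1L, max_iter = 200L, tol = 1e-6) {
  n <- nrow(x)
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- tcrossprod(xc) / (ncol(xc) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  if (is.null(n_comp)) n_comp <- rank
  n_comp <- min(n_comp, rank)
  d <- eg$values[seq_len(n_comp)]
  Ewh <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  K <- diag(1 / sqrt(d), n_comp) %*% t(Ewh)      # whitening (n_comp x n)
  z <- K %*% xc

  set.seed(seed)
  W <- matrix(stats::rnorm(n_comp^2), n_comp)
  W <- svd(W)$u %*% t(svd(W)$v)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  converged <- FALSE
  it <- 0L
  m <- ncol(z)
  while (it < max_iter) {
    it <- it + 1L
    wx <- W %*% z
    g <- tanh(wx)
    gp <- 1 - g^2
    W1 <- g %*% t(z) / m - diag(rowMeans(gp), n_comp) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  sources <- W %*% z
  mixing <- Ewh %*% diag(sqrt(d), n_comp) %*% t(W)
  list(sources = sources, mixing = mixing, unmixing = W %*% K,
       center = ctr, converged = converged, iterations = it)
}

# bipolar EOG derivations re-referenced to the nearest frontal EEG site,
# so the cerebral field is common-mode and cancels while the steep ocular
# gradient survives
bipolar_eog <- function(rec, sensors) {
  eeg <- which(rec$roles == "eeg")
  iv <- which(rec$roles == "eog_v")
  ih <- which(rec$roles == "eog_h")
  if (!length(iv) || !length(ih)) stop("no EOG channels present")
  pos <- sensors$positions
  eegpos <- pos[eeg, , drop = FALSE]
  nearest <- function(i) which.min(colSums((t(eegpos) - pos[i, ])^2))
  list(v = rec$data[iv, ] - rec$data[eeg[nearest(iv)], ],
       h = rec$data[ih, ] - rec$data[eeg[nearest(ih)], ])
}

#' Reject ocular ICA components
#'
#' Decomposes the retained EEG channels with [fast_ica()], zeroes every
#' component whose absolute Pearson correlation with either re-referenced
#' (bipolar) EOG derivation reaches `threshold`, and reconstructs the data.
#' Zero rejected components is a valid outcome.
#'
#' @param rec an `eeg_recording` with EOG channels
#' @param sensors optional `sensor_array` for the bipolar derivations; if
#'   missing, the raw EOG channels are used as derivations
#' @param threshold absolute correlation threshold (r = 0.3)
#' @param seed seed passed to [fast_ica()]
#' @param n_comp number of components (default: retained EEG channel count)
#' @return the cleaned `eeg_recording`; rejection details in `log$ica`
#' @export
reject_ocular_components <- function(rec, sensors = NULL, threshold = 0.3,
                                     seed = 1L, n_comp = NULL) {
  eeg <- which(rec$roles == "eeg" & !(rec$labels %in% rec$bad))
  if (!any(rec$roles == "eog_v") || !any(rec$roles == "eog_h"))
    stop("no EOG channels present")
  eogs <- if (is.null(sensors)) {
    list(v = rec$data[which(rec$roles == "eog_v")[1L], ],
         h = rec$data[which(rec$roles == "eog_h")[1L], ])
  } else bipolar_eog(rec, sensors)
  ic <- fast_ica(rec$data[eeg, , drop = FALSE], n_comp = n_comp, seed = seed)
  rv <- suppressWarnings(apply(ic$sources, 1L, stats::cor, y = eogs$v))
  rh <- suppressWarnings(apply(ic$sources, 1L, stats::cor, y = eogs$h))
  rv[!is.finite(rv)] <- 0; rh[!is.finite(rh)] <- 0
  reject <- which(pmax(abs(rv), abs(rh)) >= threshold)
  if (length(reject)) {
    keep_src <- ic$sources
    keep_src[reject, ] <- 0
    rec$data[eeg, ] <- ic$mixing %*% keep_src + ic$center
  }
  rec$log$stages <- c(rec$log$stages, "ica_rejection")
  rec$log$ica <- list(n_components = nrow(ic$sources),
                      rejected = reject,
                      cor_veog = rv, cor_heog = rh,
                      converged = ic$converged)
  rec
}
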