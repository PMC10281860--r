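# Batched LSTM with sequence-length masking and full backpropagation
# through time, plus the bidirectional stacked encoder used by the window
# scorer.  Sequences are held as 3D arrays [N, T, d] (records x time x
# features); rows shorter than T are padded and the pad positions masked
# so the recurrent state is held constant past each row's length.  The
# time-step loop (forward and BPTT) runs in compiled code (src/lstm.cpp)
# on [N, d, T] cubes; these wrappers handle the layout permutation.  The
# backward direction of the encoder is realised by reversing each row
# within its valid length, running the same forward machinery, and
# reversing the outputs back; the reversal is an involution, so gradients
# flow through it by applying it again.

lstm_init <- function(input_dim, H) {
  # gates ordered i, f, g, o; forget-gate bias starts at 1
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1
  list(W = glorot(input_dim, 4 * H), U = glorot(H, 4 * H), b = b)
}

# Reverse each row of A [N, T, d] within its valid length; pads stay put.
reverse_sequences <- function(A, lens) {
  d <- dim(A)
  N <- d[1]; T_ <- d[2]; k <- d[3]
  P <- matrix(rep(seq_len(T_), each = N), N, T_)       # P[i, t] = t
  for (i in seq_len(N)) {
    l <- lens[i]
    if (l > 1L) P[i, 1:l] <- l:1
  }
  base <- matrix(seq_len(N), N, T_) + (P - 1L) * N
  idx <- as.vector(base) + rep((seq_len(k) - 1L) * N * T_, each = N * T_)
  array(A[idx], d)
}

# Forward pass over A [N, T, din].  The input projection X W + b is one
# large GEMM here; the compiled loop handles the recurrent part.
# Returns per-timestep hidden states H [N, T, H], the final state (h at
# each row's last valid position) and the compiled-side cache for BPTT.
lstm_forward <- function(A, lens, par, want_cache = TRUE) {
  d <- dim(A)
  N <- d[1]; T_ <- d[2]
  M <- matrix(A, N * T_, d[3])          # row (i, t) = A[i, t, ]; free layout
  ZX <- M %*% par$W                     # bias added in compiled code
  H <- length(par$b) %/% 4L
  res <- lstm_forward_cpp(ZX, par$U, par$b, as.integer(lens), N,
                          want_cache)
  Harr <- res$H
  dim(Harr) <- c(N, T_, H)              # flat [N, T, H] layout: free
  list(H = Harr, h_final = res$h_final, Hflat = res$H,
       cache = res$cache, mask_needed = res$mask_needed,
       M = M, N = N, T_ = T_, lens = lens)
}

# BPTT.  dH: gradient wrt the per-timestep outputs [N, T, H] (or NULL),
# dh_final: gradient wrt the final state [N, H] (or NULL).  The
# compiled side returns the pre-activation gradients dZ; input-side
# gradients are recovered with large GEMMs.
lstm_backward <- function(fwd, par, dH = NULL, dh_final = NULL) {
  if (!is.null(dH)) dim(dH) <- NULL     # flat layout matches [N, T, H]
  res <- lstm_backward_cpp(fwd$Hflat, fwd$cache, fwd$mask_needed,
                           par$U, as.integer(fwd$lens), fwd$N,
                           dH, dh_final)
  dZflat <- res$dZ
  dim(dZflat) <- c(fwd$N * fwd$T_, 4L * nrow(par$U))
  dA <- dZflat %*% t(par$W)
  dim(dA) <- c(fwd$N, fwd$T_, nrow(par$W))
  list(dA = dA, dW = crossprod(fwd$M, dZflat), dU = res$dU,
       db = colSums(dZflat))
}

# ---- bidirectional layer --------------------------------------------------

bilstm_forward <- function(A, lens, par_f, par_b, want_cache = TRUE) {
  fwd <- lstm_forward(A, lens, par_f, want_cache)
  Ar <- reverse_sequences(A, lens)
  bwd <- lstm_forward(Ar, lens, par_b, want_cache)
  N <- dim(A)[1]; T_ <- dim(A)[2]
  H <- length(par_f$b) %/% 4L
  out <- array(0, c(N, T_, 2L * H))
  out[, , 1:H] <- fwd$H
  out[, , (H + 1):(2 * H)] <- reverse_sequences(bwd$H, lens)
  list(out = out, h_final = cbind(fwd$h_final, bwd$h_final),
       fwd = fwd, bwd = bwd)
}

bilstm_backward <- function(bi, par_f, par_b,
                            dOut = NULL, dh_final = NULL) {
  H <- length(par_f$b) %/% 4L
  lens <- bi$fwd$lens
  dHf <- if (is.null(dOut)) NULL else dOut[, , 1:H, drop = FALSE]
  dHb <- if (is.null(dOut)) NULL else
    reverse_sequences(dOut[, , (H + 1):(2 * H), drop = FALSE], lens)
  dhf_fin <- if (is.null(dh_final)) NULL else
    dh_final[, 1:H, drop = FALSE]
  dhb_fin <- if (is.null(dh_final)) NULL else
    dh_final[, (H + 1):(2 * H), drop = FALSE]
  gf <- lstm_backward(bi$fwd, par_f, dH = dHf, dh_final = dhf_fin)
  gb <- lstm_backward(bi$bwd, par_b, dH = dHb, dh_final = dhb_fin)
  dA <- gf$dA + reverse_sequences(gb$dA, lens)
  list(dA = dA,
       fwd = list(dW = gf$dW, dU = gf$dU, db = gf$db),
       bwd = list(dW = gb$dW, dU = gb$dU, db = gb$db))
}
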