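# Compositional treatment embeddings and the embedding-space regularizers.

#' Compositional treatment embedding
#'
#' `e(a) = E_sym(alpha(a)) + E_spec(a)`: a class-shared prototype plus a
#' treatment-specific offset, so pharmacologically related treatments share
#' parameters while retaining individual behaviour.
#'
#' @param a treatment id(s).
#' @param params a `td_params`.
#' @return an m-vector, or a matrix of row vectors for several ids.
#' @export
embed_treatment <- function(a, params) {
  idx <- treatment_index(a, params$ontology)
  E <- vocab_embeddings(params$gen, params$class_idx)
  out <- E[idx, , drop = FALSE]
  if (length(a) == 1L) as.vector(out) else out
}

# AD-capable cores used both by the public functions and the training loss --

margin_loss_core <- function(Evocab, ontology, delta) {
  pairs <- intra_class_pairs(ontology)
  if (!ncol(pairs)) return(if (is_advar(Evocab)) ad_mul(0, ad_sum(Evocab)) else 0)
  Ei <- ad_rows(Evocab, pairs[1, ])
  Ej <- ad_rows(Evocab, pairs[2, ])
  d2 <- ad_rowsums(ad_square(ad_sub(Ei, Ej)))
  ad_sum(ad_relu(ad_sub(d2, delta)))
}

align_loss_core <- function(Evocab, ontology) {
  n <- length(ontology$vocabulary)
  if (n < 2L) return(if (is_advar(Evocab)) ad_mul(0, ad_sum(Evocab)) else 0)
  pairs <- utils::combn(n, 2L)
  Ei <- ad_rows(Evocab, pairs[1, ])
  Ej <- ad_rows(Evocab, pairs[2, ])
  d2 <- ad_rowsums(ad_square(ad_sub(Ei, Ej)))
  target <- matrix(1 - ontology$kernel[cbind(pairs[1, ], pairs[2, ])], ncol = 1L)
  ad_sum(ad_square(ad_sub(d2, target)))
}

#' Intra-class margin loss on treatment embeddings
#'
#' `sum over unordered intra-class pairs of max(0, ||e(a_i) - e(a_j)||^2 - delta)`:
#' a margin-based metric-learning penalty keeping same-class treatments
#' within squared distance `delta` of each other. Zero when no class has two
#' members or when every pair is within the margin.
#'
#' @param params a `td_params`.
#' @param delta margin (>= 0); defaults to the value in `priors` if given.
#' @export
symbolic_margin_loss <- function(params, delta = 0.1) {
  E <- vocab_embeddings(params$gen, params$class_idx)
  margin_loss_core(E, params$ontology, delta)
}

#' Kernel-alignment loss on treatment embeddings
#'
#' `sum over unordered pairs of (||e(a_i) - e(a_j)||^2 - (1 - K(a_i, a_j)))^2`:
#' squared embedding distances are pulled toward the dissimilarity implied by
#' the affinity kernel, so embedding geometry mirrors the ontology.
#'
#' @param params a `td_params`.
#' @export
kernel_alignment_loss <- function(params) {
  E <- vocab_embeddings(params$gen, params$class_idx)
  align_loss_core(E, params$ontology)
}

#' Class-attention distribution for a latent state
#'
#' Softmax-normalised inner products between the (projected) latent state and
#' the class prototype embeddings `e_c = E_sym(c)`. The latent is passed
#' through the learned projection only when `d_z != m`.
#'
#' @param z latent vector (length d_z).
#' @param params a `td_params`.
#' @return a probability vector named by class; entries positive, sum 1.
#' @export
class_attention <- function(z, params) {
  if (!length(params$ontology$classes)) stop("ontology has no classes")
  a <- attention_rows(matrix(z, nrow = 1L), params$gen, params)
  stats::setNames(as.vector(a), params$ontology$classes)
}

#' Negative attention entropy
#'
#' Returns `-H(alpha) = sum_c alpha_c log alpha_c` (with `0 log 0 = 0`), in
#' `[-log |V|, 0]`. Added to a minimised objective with positive weight it
#' rewards entropy, discouraging over-concentration of class attention.
#'
#' @param attention a probability vector.
#' @export
attention_entropy_penalty <- function(attention) {
  stopifnot(abs(sum(attention) - 1) < 1e-6, all(attention >= 0))
  p <- attention[attention > 0]
  sum(p * log(p))
}

# batched negative entropy of attention rows (AD)
neg_entropy_rows <- function(alpha, eps = 1e-12) {
  ad_rowsums(ad_mul(alpha, ad_log(ad_add(alpha, eps))))
}

#' Export embeddings as a tidy table
#'
#' @param params a `td_params`.
#' @return a tibble with `treatment`, `class`, and embedding columns `e1..em`.
#' @export
embedding_table <- function(params) {
  E <- vocab_embeddings(params$gen, params$class_idx)
  colnames(E) <- paste0("e", seq_len(ncol(E)))
  dplyr::bind_cols(tibble::tibble(treatment = params$ontology$vocabulary,
                                  class = unname(params$ontology$class_of)),
                   tibble::as_tibble(E))
}
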