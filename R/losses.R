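# The training objective: adversarial loss (binary cross-entropy on patch
# logits), discriminator feature matching, and a blurred color loss, all
# evaluated on normalized-Lab images. Total generator objective:
# L = sum_k L_GAN(G, D_k) + alpha * sum_k L_FM(G, D_k) + beta * L_color(G).

#' Loss weights
#' @param alpha Feature-matching weight (default 10).
#' @param beta Color-loss weight (default 0.001).
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 10, beta = 0.001) {
  if (alpha < 0 || beta < 0) stop("loss weights must be nonnegative")
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

# mean BCE-with-logits against a constant target of 1 (or 0)
bce_logits <- function(logits, target_one) {
  # softplus(-x) for target 1, softplus(x) for target 0
  if (target_one) ag_mean(ag_softplus(ag_neg(logits)))
  else ag_mean(ag_softplus(logits))
}

#' Adversarial loss on patch logits
#'
#' Binary cross-entropy with logits, numerically stable. In the
#' `"discriminator"` role, the mean of the real-to-one and fake-to-zero
#' terms; in the `"generator"` role, the non-saturating fake-to-one term.
#' All-zero logits give ln 2 per term.
#'
#' @param logits_real,logits_fake Raw logit maps (nodes or arrays);
#'   `logits_real` is ignored in the generator role.
#' @param role `"discriminator"` or `"generator"`.
#' @return Scalar loss node.
#' @export
adversarial_loss <- function(logits_real = NULL, logits_fake,
                             role = c("discriminator", "generator")) {
  role <- match.arg(role)
  if (length(ag_value(logits_fake)) == 0L) stop("empty logit map")
  if (role == "generator") return(bce_logits(as_node(logits_fake), TRUE))
  if (is.null(logits_real) || length(ag_value(logits_real)) == 0L)
    stop("empty logit map")
  ag_scale(ag_add(bce_logits(as_node(logits_real), TRUE),
                  bce_logits(as_node(logits_fake), FALSE)), 0.5)
}

#' Discriminator feature-matching loss
#'
#' Sum over discriminator stages of the per-element L1 distance between the
#' features of the real pair and the generated pair:
#' sum_i ||f_real_i - f_fake_i||_1 / N_i.
#'
#' @param features_real,features_fake Equal-length lists of feature maps
#'   (the real branch is treated as a constant target).
#' @return Scalar loss node.
#' @export
feature_matching_loss <- function(features_real, features_fake) {
  if (length(features_real) != length(features_fake))
    stop("feature lists differ in length")
  total <- NULL
  for (i in seq_along(features_real)) {
    fr <- ag_value(features_real[[i]])
    fk <- features_fake[[i]]
    if (!all(dim(fr) == dim(ag_value(fk)))) stop("feature shapes differ")
    term <- ag_mean(ag_abs(ag_sub(as_node(fk), ag_const(fr))))
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  total
}

#' Blurred color loss
#'
#' Both images are blurred with a normalized Gaussian kernel (reflect
#' padding) and compared with the sum of the squared and the absolute
#' differences over all elements: ||X_b - Y_b||_2^2 + ||X_b - Y_b||_1.
#' Computed on normalized-Lab encodings so the penalty is closer to
#' perceptually uniform.
#'
#' @param X,Y Images of identical shape (nodes or arrays).
#' @param kernel A [gaussian_kernel()].
#' @return Scalar loss node.
#' @export
color_loss <- function(X, Y, kernel = gaussian_kernel()) {
  if (!all(dim(ag_value(X)) == dim(ag_value(Y)))) stop("shape mismatch")
  xb <- ag_blur(as_node(X), kernel$weights, kernel$g1)
  yb <- ag_blur(as_node(Y), kernel$weights, kernel$g1)
  d <- ag_sub(xb, yb)
  ag_add(ag_sum(ag_square(d)), ag_sum(ag_abs(d)))
}

#' Total generator objective
#'
#' `adv_g + alpha * (fm_d1 + fm_d2) + beta * color`, with the adversarial
#' term already summed over both discriminators.
#'
#' @param adv_g,fm_d1,fm_d2,color Scalar component losses (nodes or
#'   numbers).
#' @param weights A [loss_weights()].
#' @return Scalar loss node.
#' @export
total_generator_loss <- function(adv_g, fm_d1, fm_d2, color,
                                 weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  fm <- ag_add(as_node(fm_d1), as_node(fm_d2))
  ag_add(ag_add(as_node(adv_g), ag_scale(fm, weights$alpha)),
         ag_scale(as_node(color), weights$beta))
}
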