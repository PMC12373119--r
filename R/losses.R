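# Adversarial (binary cross-entropy) and L1 reconstruction losses.
# Training always evaluates the cross-entropy in the numerically stable
# combined logit form; the probability-space entry points below expose the
# printed formulas directly.

# stable BCE with logits against constant label y in {0,1}; returns the
# per-element mean loss and the gradient w.r.t. the logits
.bceWithLogits <- function(z, y) {
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  grad <- (1 / (1 + exp(-z)) - y) / length(z)
  list(loss = loss, grad = grad)
}

#' Discriminator loss
#'
#' Binary cross-entropy over a batch:
#' -(1/N) * sum( log D(x_i) + log(1 - D(G(L_i))) ),
#' i.e. real samples labelled 1 and generated samples labelled 0.  A perfect
#' discriminator scores 0; an indifferent one (both probabilities 0.5)
#' scores 2*ln 2.
#'
#' @param realScores discriminator outputs on real images.
#' @param fakeScores discriminator outputs on generated images (same length).
#' @param logits if `TRUE` the inputs are logits and the loss is evaluated
#'   in the numerically stable combined form; otherwise they are
#'   probabilities in (0, 1).
#' @return scalar loss.
#' @export
discriminatorLoss <- function(realScores, fakeScores, logits = FALSE) {
  if (length(realScores) == 0L || length(fakeScores) == 0L)
    stop("empty batch")
  if (logits) {
    .bceWithLogits(realScores, 1)$loss + .bceWithLogits(fakeScores, 0)$loss
  } else {
    -mean(log(realScores)) - mean(log1p(-fakeScores))
  }
}

#' Generator loss
#'
#' Sum of the adversarial term -(1/N) * sum(log D(G(L_i))) (the generator is
#' rewarded when the discriminator scores its output as real) and lambda
#' times the L1 reconstruction term (1/N) * sum |G(L_i) - C_i|, reduced as
#' the mean absolute deviation per element so that lambda is
#' resolution-independent.
#'
#' @param fakeScores discriminator outputs on generated images.
#' @param generated generated a*/b* planes (any numeric array).
#' @param target ground-truth a*/b* planes, same shape.
#' @param lambda non-negative weight of the L1 term (default 100).
#' @param logits if `TRUE`, `fakeScores` are logits.
#' @return list with `total`, `adversarial` and `l1` components.
#' @export
generatorLoss <- function(fakeScores, generated, target, lambda = 100,
                          logits = FALSE) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (!identical(dim(generated) %||% length(generated),
                 dim(target) %||% length(target)))
    stop("generated and target planes are misaligned")
  adv <- if (logits) .bceWithLogits(fakeScores, 1)$loss
         else -mean(log(fakeScores))
  l1 <- mean(abs(generated - target))
  list(total = adv + lambda * l1, adversarial = adv, l1 = l1)
}
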