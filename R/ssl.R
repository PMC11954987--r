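#' Plan masked-patch manipulation for one window
#'
#' Each time slot is independently selected for manipulation with
#' probability `p_mask` (default 0.3). Every selected slot is assigned one
#' action — replace by the learned mask token, replace by a random embedded
#' patch from the batch, or keep unchanged — with the 80/10/10 BERT ratios.
#' One action per slot, shared by the patches of all channels at that slot:
#' masking whole time slices prevents the trivial solution of interpolating
#' a single masked sensor from its spatial neighbours.
#'
#' @param n_slots Number of time slots.
#' @param p_mask Per-slot selection probability in `[0, 1]`.
#' @param ratios Probabilities of the (mask, random, keep) actions;
#'   must sum to 1.
#' @return A `mask_plan`: list with integer `slots`, parallel character
#'   `actions`, and the parameters used.
#' @export
plan_mask <- function(n_slots, p_mask = 0.3, ratios = c(0.8, 0.1, 0.1)) {
  if (p_mask < 0 || p_mask > 1) stop("invalid parameter: p_mask must lie in [0, 1]")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
    stop("invalid parameter: action ratios must sum to 1")
  sel <- which(stats::runif(n_slots) < p_mask)
  actions <- if (length(sel))
    sample(c("mask", "random", "keep"), length(sel), replace = TRUE,
           prob = ratios)
  else character(0)
  structure(list(slots = sel, actions = actions, p_mask = p_mask,
                 ratios = ratios, n_slots = as.integer(n_slots)),
            class = "mask_plan")
}

#' Corrupt embedded patches according to a mask plan
#'
#' Operates after the linear embedding and before positional embeddings are
#' added; the classification token is never touched. Mask-action slots are
#' replaced by the learned mask token; random-action slots by uniformly
#' drawn rows of `pool` (embedded patches of the current batch, treated as
#' constants in the backward pass); keep-action slots are left unchanged but
#' still count as manipulated for the reconstruction loss.
#'
#' @param emb N x d_model embedded patches of one window.
#' @param slot Per-patch time-slot index (parallel to the rows of `emb`).
#' @param plan A [plan_mask()] result.
#' @param mask_token 1 x d_model learned mask vector.
#' @param pool Matrix of embedded patches to draw random replacements from
#'   (defaults to `emb` itself).
#' @return List with `emb` (corrupted matrix), `manipulated` (row indices
#'   entering the loss) and `masked_rows` (rows set to the mask token).
#' @export
corrupt_tokens <- function(emb, slot, plan, mask_token, pool = emb) {
  stopifnot(inherits(plan, "mask_plan"))
  masked_rows <- integer(0)
  random_rows <- integer(0)
  for (k in seq_along(plan$slots)) {
    rows <- which(slot == plan$slots[k])
    if (!length(rows)) next
    act <- plan$actions[k]
    if (act == "mask") {
      emb[rows, ] <- matrix(mask_token, length(rows), ncol(emb), byrow = TRUE)
      masked_rows <- c(masked_rows, rows)
    } else if (act == "random") {
      src <- sample.int(nrow(pool), length(rows), replace = TRUE)
      emb[rows, ] <- pool[src, , drop = FALSE]
      random_rows <- c(random_rows, rows)
    }
  }
  list(emb = emb,
       manipulated = which(slot %in% plan$slots),
       masked_rows = masked_rows,
       random_rows = random_rows)
}

#' Cosine reconstruction loss
#'
#' `recon_loss(x_hat, x) = 1 - (x . x_hat) / (||x|| ||x_hat||)`, in `[0, 2]`
#' and scale-invariant in each argument. `batch_recon_loss` averages it over
#' the manipulated patches only.
#'
#' @param x_hat,x Reconstructed and original patch (D-vectors), both
#'   non-zero.
#' @return Scalar loss.
#' @export
recon_loss <- function(x_hat, x) {
  nh <- sqrt(sum(x_hat^2)); nx <- sqrt(sum(x^2))
  if (nh == 0 || nx == 0)
    stop("degenerate patch: zero-norm vector in cosine reconstruction loss")
  1 - sum(x_hat * x) / (nh * nx)
}

#' @rdname recon_loss
#' @param recons,originals N x D matrices of reconstructed and original
#'   patches.
#' @param manipulated Row indices entering the loss.
#' @export
batch_recon_loss <- function(recons, originals, manipulated) {
  if (!length(manipulated)) return(0)
  mean(vapply(manipulated, function(i)
    recon_loss(recons[i, ], originals[i, ]), numeric(1)))
}

# Gradient of recon_loss with respect to x_hat (x treated as the target).
recon_loss_grad <- function(x_hat, x) {
  nh <- sqrt(sum(x_hat^2)); nx <- sqrt(sum(x^2))
  cosv <- sum(x_hat * x) / (nh * nx)
  -(x / (nh * nx) - cosv * x_hat / nh^2)
}
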