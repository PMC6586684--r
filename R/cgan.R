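## Conditional GAN for EPs reconstruction: U-Net generator translating
## (|B1+|, phase, auxiliary) image triplets into a normalized property map,
## and a PatchGAN discriminator scoring local patches of (input, map) stacks.

#' Network configuration for the cGAN reconstructor
#'
#' Loss weights default to the combination selected on the validation
#' phantoms: adversarial weight 2, L1 weight 100, L2 weight 200. The tumor
#' generalization experiment uses the boundary-sharpening combination
#' (2, 1000, 2000).
#'
#' @param target which property the network reconstructs: `"sigma"` or
#'   `"epsr"`; separate networks are trained for the two
#' @param lambda_gan,lambda_l1,lambda_l2 non-negative loss weights;
#'   `lambda_gan = 0` degenerates to plain U-Net regression
#' @param image_size square image side in voxels
#' @param depth number of U-Net resolution levels
#' @param base_channels channel width of the first encoder level
#' @param d_channels base width of the PatchGAN discriminator
#' @param epochs,batch_size,learning_rate,beta1 Adam training hyperparameters
#' @param seed master seed for initialization and example shuffling
#' @param mask_weight extra weight given to object voxels in the L1/L2
#'   regression terms (air is the easy, dominant class; weighting the object
#'   region makes the small-sample regime converge on tissue values)
#' @param collapse_nrmse training occasionally stalls in a mode that
#'   predicts the dataset-mean property; runs whose validation NRMSE still
#'   exceeds this threshold three quarters of the way through training are
#'   abandoned and restarted from a derived seed (validation-based run
#'   screening, in the same spirit as the validation-NRMSE model selection)
#' @param max_restarts restart budget for collapse detection
#' @param sigma_range,epsr_range physical ranges mapped linearly onto the
#'   network's `[0, 1]` target scale
#' @return a `network_config`
#' @export
network_config <- function(target = c("sigma", "epsr"),
                           lambda_gan = 2, lambda_l1 = 100, lambda_l2 = 200,
                           image_size = 64, depth = 4, base_channels = 8,
                           d_channels = 4,
                           epochs = 20, batch_size = 5,
                           learning_rate = 2e-4, beta1 = 0.5, seed = 1,
                           mask_weight = 4,
                           collapse_nrmse = 0.18, max_restarts = 1,
                           sigma_range = c(0, 2.5), epsr_range = c(1, 100)) {
  target <- match.arg(target)
  if (lambda_gan < 0 || lambda_l1 < 0 || lambda_l2 < 0)
    stop("loss weights must be non-negative")
  structure(list(target = target, lambda_gan = lambda_gan,
                 lambda_l1 = lambda_l1, lambda_l2 = lambda_l2,
                 image_size = image_size, depth = depth,
                 base_channels = base_channels, d_channels = d_channels,
                 epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 beta1 = beta1, seed = seed, mask_weight = mask_weight,
                 collapse_nrmse = collapse_nrmse, max_restarts = max_restarts,
                 sigma_range = sigma_range, epsr_range = epsr_range),
            class = "network_config")
}

.target_range <- function(config) {
  if (config$target == "sigma") config$sigma_range else config$epsr_range
}

## ---- U-Net generator -------------------------------------------------

unet_init <- function(image_size, depth = 4, nb = 8, in_ch = 3) {
  ch <- nb * 2^(seq_len(depth) - 1)
  mods <- list()
  cin <- in_ch
  for (l in seq_len(depth)) {
    mods[[l]] <- nn_conv(cin, ch[l], k = 4, stride = 2, pad = 1,
                         norm = l > 1, act = "lrelu")
    cin <- ch[l]
  }
  for (l in seq(depth, 2)) {
    cin_l <- if (l == depth) ch[l] else 2 * ch[l]
    mods[[depth + (depth - l + 1)]] <-
      nn_conv(cin_l, ch[l - 1], k = 3, stride = 1, pad = 1,
              norm = TRUE, act = "relu")
  }
  mods[[2 * depth]] <- nn_conv(2 * ch[1], ch[1], k = 3, stride = 1, pad = 1,
                               norm = FALSE, act = "relu")
  mods[[2 * depth + 1]] <- nn_conv(ch[1], 1, k = 3, stride = 1, pad = 1,
                                   norm = FALSE, act = "linear")
  list(mods = mods, depth = depth, image_size = image_size, in_ch = in_ch)
}

unet_forward <- function(net, x, B = 1L) {
  depth <- net$depth
  H <- net$image_size; W <- net$image_size
  skips <- vector("list", depth)
  caches <- vector("list", length(net$mods))
  cur <- x
  for (l in seq_len(depth)) {
    r <- conv_forward(net$mods[[l]], cur, H, W, B)
    caches[[l]] <- r$cache
    H <- r$H; W <- r$W
    skips[[l]] <- r$y
    cur <- r$y
  }
  for (l in seq(depth, 2)) {
    i <- depth + (depth - l + 1)
    u <- up2_forward(cur, H, W, B)
    cur <- u$y; H <- u$H; W <- u$W
    r <- conv_forward(net$mods[[i]], cur, H, W, B)
    caches[[i]] <- r$cache
    cur <- cbind(r$y, skips[[l - 1]])
  }
  u <- up2_forward(cur, H, W, B)
  cur <- u$y; H <- u$H; W <- u$W
  r <- conv_forward(net$mods[[2 * depth]], cur, H, W, B)
  caches[[2 * depth]] <- r$cache
  r2 <- conv_forward(net$mods[[2 * depth + 1]], r$y, H, W, B)
  caches[[2 * depth + 1]] <- r2$cache
  list(y = r2$y, caches = caches, B = B)
}

unet_backward <- function(net, fwd, dy) {
  depth <- net$depth
  B <- fwd$B
  mods <- net$mods
  grads <- list()
  n <- net$image_size
  b <- conv_backward(mods[[2 * depth + 1]], fwd$caches[[2 * depth + 1]], dy)
  grads[[paste(2 * depth + 1, "W", sep = ".")]] <- b$dW
  grads[[paste(2 * depth + 1, "b", sep = ".")]] <- b$db
  b2 <- conv_backward(mods[[2 * depth]], fwd$caches[[2 * depth]], b$dx)
  grads[[paste(2 * depth, "W", sep = ".")]] <- b2$dW
  grads[[paste(2 * depth, "b", sep = ".")]] <- b2$db
  cur <- up2_backward(b2$dx, n %/% 2L, n %/% 2L, B)
  dskip <- vector("list", depth)   # gradient flowing into each skip tensor
  for (l in seq(2, depth)) {
    i <- depth + (depth - l + 1)
    ch_lm1 <- mods[[i]]$cout
    dconv <- cur[, seq_len(ch_lm1), drop = FALSE]
    dskip[[l - 1]] <- cur[, ch_lm1 + seq_len(ncol(cur) - ch_lm1),
                          drop = FALSE]
    b <- conv_backward(mods[[i]], fwd$caches[[i]], dconv)
    for (nm in c("W", "b", "g", "gb"))
      if (!is.null(b[[paste0("d", nm)]]))
        grads[[paste(i, nm, sep = ".")]] <- b[[paste0("d", nm)]]
    hl <- n %/% 2L^l
    cur <- up2_backward(b$dx, hl, hl, B)
    if (l == depth) dskip[[depth]] <- cur
  }
  dcur <- dskip[[depth]]
  for (l in seq(depth, 1)) {
    if (l < depth) dcur <- dcur + dskip[[l]]
    b <- conv_backward(mods[[l]], fwd$caches[[l]], dcur, need_dx = l > 1)
    for (nm in c("W", "b", "g", "gb"))
      if (!is.null(b[[paste0("d", nm)]]))
        grads[[paste(l, nm, sep = ".")]] <- b[[paste0("d", nm)]]
    dcur <- b$dx
  }
  grads
}

## ---- PatchGAN discriminator ------------------------------------------

patchgan_init <- function(image_size, nb = 8, in_ch = 4) {
  list(mods = list(
    nn_conv(in_ch, 2 * nb, k = 4, stride = 2, pad = 1, norm = FALSE,
            act = "lrelu"),
    nn_conv(2 * nb, 4 * nb, k = 4, stride = 2, pad = 1, norm = TRUE,
            act = "lrelu"),
    nn_conv(4 * nb, 1, k = 4, stride = 1, pad = 1, norm = FALSE,
            act = "linear")
  ), image_size = image_size, in_ch = in_ch)
}

patchgan_forward <- function(dnet, x, B = 1L) {
  H <- dnet$image_size; W <- dnet$image_size
  caches <- vector("list", 3)
  cur <- x
  for (i in 1:3) {
    r <- conv_forward(dnet$mods[[i]], cur, H, W, B)
    caches[[i]] <- r$cache
    cur <- r$y; H <- r$H; W <- r$W
  }
  list(z = cur, caches = caches)
}

patchgan_backward <- function(dnet, fwd, dz, need_input_grad = FALSE,
                              need_weights = TRUE) {
  grads <- list()
  cur <- dz
  for (i in 3:1) {
    b <- conv_backward(dnet$mods[[i]], fwd$caches[[i]], cur,
                       need_dx = i > 1 || need_input_grad,
                       need_weights = need_weights)
    for (nm in c("W", "b", "g", "gb"))
      if (!is.null(b[[paste0("d", nm)]]))
        grads[[paste(i, nm, sep = ".")]] <- b[[paste0("d", nm)]]
    cur <- b$dx
  }
  list(grads = grads, dx = cur)
}

## ---- objective -------------------------------------------------------

#' Conditional GAN training objective
#'
#' The weighted sum of the adversarial patch objective and the L1 and L2
#' distances between the generated map and the ground truth, evaluated the
#' way the training loop uses it.
#'
#' @param G_output,target numeric arrays of identical shape (normalized maps)
#' @param D_scores optional list with elements `real` and `fake`: patch
#'   probabilities in (0, 1) from the discriminator; `NULL` with
#'   `lambda_gan = 0` gives the plain U-Net regression objective
#' @param config a [network_config()]
#' @return list with `generator` and `discriminator` scalar losses (the
#'   discriminator entry is `NA` without patch scores)
#' @export
cgan_objective <- function(G_output, target, D_scores = NULL, config) {
  if (!all(dim(G_output) == dim(target)) &&
      length(G_output) != length(target))
    stop("generator output and target shapes differ")
  diff <- G_output - target
  l1 <- mean(abs(diff))
  l2 <- mean(diff^2)
  adv <- 0
  dloss <- NA_real_
  if (config$lambda_gan > 0) {
    if (is.null(D_scores))
      stop("lambda_gan > 0 requires discriminator patch scores")
    adv <- -mean(log(pmax(D_scores$fake, 1e-12)))
    dloss <- -mean(log(pmax(D_scores$real, 1e-12))) -
      mean(log(pmax(1 - D_scores$fake, 1e-12)))
  }
  list(generator = config$lambda_gan * adv + config$lambda_l1 * l1 +
         config$lambda_l2 * l2,
       discriminator = dloss)
}

## ---- training --------------------------------------------------------

## Normalized validation error used for collapse screening: masked RMSE of
## the generator output against the target, relative to the target mean.
.probe_nrmse <- function(G, validation) {
  mean(vapply(validation, function(ex) {
    yhat <- unet_forward(G, ex$x)$y
    m <- as.vector(ex$mask)
    sqrt(mean((yhat[m] - ex$y[m])^2)) / mean(ex$y[m])
  }, numeric(1)))
}

## Core optimization: alternating discriminator/generator Adam updates.
## examples: list of list(x = (HW, 3) input, y = (HW, 1) normalized target).
## A validation probe a quarter of the way through training abandons
## mean-collapsed runs and restarts from a derived seed.
train_cgan <- function(examples, config, validation = NULL,
                       init_G = NULL, verbose = FALSE) {
  if (length(examples) == 0) stop("empty training set")
  attempts <- 1 + max(0, config$max_restarts %||% 0)
  probe_epoch <- ceiling(0.75 * config$epochs)
  for (attempt in seq_len(attempts)) {
    res <- .train_cgan_once(examples, config,
                            seed = config$seed + 104729 * (attempt - 1),
                            init_G = init_G,
                            probe = if (attempt < attempts &&
                                        length(validation %||% list()) > 0)
                              list(epoch = probe_epoch,
                                   threshold = config$collapse_nrmse,
                                   validation = validation),
                            verbose = verbose)
    if (!isTRUE(res$collapsed)) {
      res$attempts <- attempt
      return(res)
    }
    if (verbose)
      message("validation probe flagged a collapsed run; restarting")
  }
  res$attempts <- attempts
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.train_cgan_once <- function(examples, config, seed, init_G = NULL,
                             probe = NULL, verbose = FALSE) {
  n_px <- config$image_size^2
  with_seed(seed, {
    G <- if (is.null(init_G)) unet_init(config$image_size, config$depth,
                                        config$base_channels)
         else init_G
    use_D <- config$lambda_gan > 0
    D <- if (use_D) patchgan_init(config$image_size, config$d_channels)
    optG <- adam_init(.module_params(G$mods))
    optD <- if (use_D) adam_init(.module_params(D$mods))
    tG <- 0; tD <- 0
    history <- data.frame(epoch = integer(), loss_g = numeric(),
                          loss_l1 = numeric(), loss_d = numeric())
    bs <- max(1L, config$batch_size)
    for (epoch in seq_len(config$epochs)) {
      ## constant rate for the first half, linear decay to 0 afterwards
      lr <- config$learning_rate *
        min(1, 2 * (1 - (epoch - 1) / config$epochs))
      ord <- sample(length(examples))
      batches <- split(ord, ceiling(seq_along(ord) / bs))
      acc_g <- 0; acc_l1 <- 0; acc_d <- 0
      for (bi in batches) {
        B <- length(bi)
        x <- do.call(rbind, lapply(examples[bi], `[[`, "x"))
        y <- do.call(rbind, lapply(examples[bi], `[[`, "y"))
        w <- 1 + config$mask_weight *
          unlist(lapply(examples[bi], function(e) as.vector(e$mask)))
        w <- w / mean(w)
        fwdG <- unet_forward(G, x, B)
        yhat <- fwdG$y
        diff <- yhat - y
        if (use_D) {
          ## one batched discriminator pass over (input, real) stacked on
          ## (input, fake); its cache serves both the D update and the
          ## generator's adversarial gradient (through the pre-update D)
          fwd_d <- patchgan_forward(D, rbind(cbind(x, y), cbind(x, yhat)),
                                    2L * B)
          half <- length(fwd_d$z) %/% 2L
          z_r <- fwd_d$z[seq_len(half)]
          z_f <- fwd_d$z[half + seq_len(half)]
          ld <- 0.5 * (bce_logits(z_r, 1) + bce_logits(z_f, 0))
          gr <- patchgan_backward(D, fwd_d,
                                  matrix(c(0.5 * bce_logits_grad(z_r, 1),
                                           0.5 * bce_logits_grad(z_f, 0)),
                                         ncol = 1))
          la <- bce_logits(z_f, 1)
          bD <- patchgan_backward(D, fwd_d,
                                  matrix(c(rep(0, half),
                                           bce_logits_grad(z_f, 1)),
                                         ncol = 1),
                                  need_input_grad = TRUE,
                                  need_weights = FALSE)
          dy_adv <- bD$dx[B * n_px + seq_len(B * n_px), 4, drop = FALSE]
          tD <- tD + 1
          up <- .apply_grads(D$mods, gr$grads, optD, lr, config$beta1,
                             0.999, tD)
          D$mods <- up$mods; optD <- up$opt
          acc_d <- acc_d + ld * B
        } else {
          la <- 0
          dy_adv <- 0
        }
        l1 <- mean(w * abs(diff)); l2 <- mean(w * diff^2)
        dy <- config$lambda_gan * dy_adv +
          w * (config$lambda_l1 * sign(diff) + config$lambda_l2 * 2 * diff) /
            (n_px * B)
        gg <- unet_backward(G, fwdG, dy)
        tG <- tG + 1
        up <- .apply_grads(G$mods, gg, optG, lr, config$beta1, 0.999, tG)
        G$mods <- up$mods; optG <- up$opt
        lg <- config$lambda_gan * la + config$lambda_l1 * l1 +
          config$lambda_l2 * l2
        if (!is.finite(lg)) stop("training diverged (non-finite loss)")
        acc_g <- acc_g + lg * B; acc_l1 <- acc_l1 + l1 * B
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss_g = acc_g / length(examples),
        loss_l1 = acc_l1 / length(examples),
        loss_d = if (use_D) acc_d / length(examples) else NA_real_))
      if (!is.null(probe) && epoch == probe$epoch) {
        pn <- .probe_nrmse(G, probe$validation)
        if (verbose) message(sprintf("probe NRMSE at epoch %d: %.3f",
                                     epoch, pn))
        if (pn > probe$threshold)
          return(list(G = G, D = D, history = history, collapsed = TRUE,
                      probe_nrmse = pn))
      }
      if (verbose)
        message(sprintf("epoch %d: G %.4f (L1 %.4f)%s", epoch,
                        history$loss_g[epoch], history$loss_l1[epoch],
                        if (use_D) sprintf(" D %.4f", history$loss_d[epoch])
                        else ""))
    }
    list(G = G, D = D, history = history)
  })
}
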