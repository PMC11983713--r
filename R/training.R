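#' Train the charge and charge-transfer networks on a dataset
#'
#' Fits the element-specific charge networks and (optionally) the pair CT
#' network on an `aq_dataset` from [make_training_set()].  CT labels are
#' divided by the cutoff gate `s_c(r_OO; ct_cutoff)` before fitting, since
#' the predictor multiplies the raw network antisymmetrization by that gate.
#'
#' @param dataset an `aq_dataset`.
#' @param hidden hidden-layer widths for all three networks.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param seed integer seed.
#' @param train_ct also train the CT network.
#' @param verbose print progress.
#' @return list of class `aq_trained`: networks `net_O`, `net_H`, `net_CT`
#'   and a `metrics` data.frame with per-element held-out MAE (e), label SD
#'   (e) and R^2.
#' @export
train_charge_model <- function(dataset, hidden = c(64, 64, 64, 64),
                               epochs = 200, lr = 1e-3, batch = 128,
                               seed = 1L, train_ct = TRUE, verbose = FALSE) {
  fit_one <- function(part, n_in, sd_offset, ygate = NULL) {
    tr <- part$split == "train"; va <- part$split == "val"
    te <- part$split == "test"
    y <- part$y
    if (!is.null(ygate)) y <- y / ygate
    net <- dense_network(n_in, hidden, seed = seed + sd_offset)
    net <- train_network(net, part$X[tr, , drop = FALSE], y[tr],
                         part$X[va, , drop = FALSE], y[va],
                         epochs = epochs, batch = batch, lr = lr,
                         seed = seed + sd_offset + 1L, verbose = verbose)
    pred <- forward_charge(net, part$X[te, , drop = FALSE])
    resid <- pred - y[te]
    list(net = net,
         mae = mean(abs(resid)),
         label_sd = sd(y[te]),
         r2 = 1 - sum(resid^2) / sum((y[te] - mean(y[te]))^2))
  }
  fO <- fit_one(dataset$O, 24, 0L)
  fH <- fit_one(dataset$H, 24, 100L)
  out <- list(net_O = fO$net, net_H = fH$net, net_CT = NULL,
              spec = dataset$spec)
  metrics <- data.frame(element = c("O", "H"),
                        mae = c(fO$mae, fH$mae),
                        label_sd = c(fO$label_sd, fH$label_sd),
                        r2 = c(fO$r2, fH$r2))
  if (train_ct && !is.null(dataset$CT$X) && nrow(dataset$CT$X) > 0) {
    gate <- cutoff_weight(dataset$CT$r_OO, dataset$spec$ct_cutoff)
    gate[gate < 1e-3] <- 1e-3
    fC <- fit_one(dataset$CT, 36, 200L, ygate = gate)
    out$net_CT <- fC$net
    metrics <- rbind(metrics, data.frame(element = "CT", mae = fC$mae,
                                         label_sd = fC$label_sd, r2 = fC$r2))
  }
  out$metrics <- metrics
  class(out) <- "aq_trained"
  out
}

#' Evaluate trained charge networks on configurations
#'
#' Computes held-out-style error statistics of the element networks against
#' surrogate labels on a list of configurations (used for the transferability
#' check across cluster sizes).
#'
#' @param trained an `aq_trained` (or list with `net_O`, `net_H`, `spec`).
#' @param frames list of configurations.
#' @param params the [surrogate_params()] that define the labels.
#' @param seed noise seed offset passed to the label generator.
#' @return data.frame with per-element MAE, label SD and R^2.
#' @export
evaluate_charge_model <- function(trained, frames, params = surrogate_params(),
                                  seed = 1L) {
  XO <- XH <- NULL; yO <- yH <- numeric(0)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    Fk <- charge_feature_vector(f, trained$spec)
    qk <- surrogate_charges(f, params, seed = seed + k)
    isO <- f$species == "O"
    XO <- rbind(XO, Fk[isO, , drop = FALSE])
    XH <- rbind(XH, Fk[!isO, , drop = FALSE])
    yO <- c(yO, qk[isO]); yH <- c(yH, qk[!isO])
  }
  stat <- function(net, X, y) {
    pred <- forward_charge(net, X)
    resid <- pred - y
    c(mae = mean(abs(resid)), label_sd = sd(y),
      r2 = 1 - sum(resid^2) / sum((y - mean(y))^2))
  }
  rbind(data.frame(element = "O", t(stat(trained$net_O, XO, yO))),
        data.frame(element = "H", t(stat(trained$net_H, XH, yH))))
}
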