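# shared fixture builders (all generated in code; nothing on disk)

make_toy_loop <- function(values, times = NULL, layout = "ceus_left") {
  nf <- length(values)
  if (is.null(times)) times <- seq(0, by = 1, length.out = nf)
  px <- array(0, c(8, 12, nf))
  for (i in seq_len(nf)) px[, , i] <- values[i]
  ceus_loop(px, times, layout = layout)
}

make_square_annotation <- function() {
  lesion_annotation(0L, rbind(c(100, 150), c(200, 150),
                              c(150, 100), c(150, 200)),
                    long_axis_mm = 20, short_axis_mm = 20)
}

make_miniloop <- function(crops, F = 4L, label = NULL, case_id = "case") {
  structure(list(crops = crops,
                 times_s = seq_len(dim(crops)[3]),
                 phase_labels = rep(c("ap", "pvp", "lp"), each = F),
                 case_id = case_id, label = label),
            class = "mini_loop")
}

tiny_model_config <- function(input_size = c(8L, 8L)) {
  model_config("small_cnn", input_size = input_size,
               cnn_channels = c(2L, 3L, 4L), lstm_hidden = 6L)
}

lognormal_params <- function(t0 = 5, baseline = 0, auc = 100,
                             mu = 2, sigma = 0.5) {
  list(t0 = t0, baseline = baseline, auc = auc, mu = mu, sigma = sigma)
}
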