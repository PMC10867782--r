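# Checkpoint archive: one file holding all submodule parameters, optimizer
# state, configs and the iteration counter; version-tagged.

param_values <- function(model) lapply(collect_params(model), function(p) p$value)

restore_params <- function(model, values) {
  ps <- collect_params(model)
  if (length(ps) != length(values)) stop("checkpoint parameter count mismatch")
  for (i in seq_along(ps)) {
    if (!identical(dim(ps[[i]]$value), dim(values[[i]])) &&
        length(ps[[i]]$value) != length(values[[i]]))
      stop("checkpoint parameter shape mismatch at index ", i)
    ps[[i]]$value <- values[[i]]
  }
  invisible(model)
}

adam_state <- function(opt) list(m = opt$m, v = opt$v, t = opt$t)

restore_adam <- function(opt, st) {
  opt$m <- st$m; opt$v <- st$v; opt$t <- st$t
  opt
}

save_checkpoint <- function(path, gen, d1, d2, opt_g, opt_d1, opt_d2,
                            iter, tconfig) {
  obj <- list(version = "tsegan-checkpoint-1",
              net_config = gen$config,
              disc_config1 = d1$config, disc_config2 = d2$config,
              train_config = tconfig, iter = iter,
              params = list(gen = param_values(gen), d1 = param_values(d1),
                            d2 = param_values(d2)),
              adam = list(g = adam_state(opt_g), d1 = adam_state(opt_d1),
                          d2 = adam_state(opt_d2)))
  saveRDS(obj, path)
  invisible(path)
}

load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "tsegan-checkpoint-1"))
    stop("unrecognized checkpoint version")
  obj
}

#' Load a trained generator from a checkpoint
#' @param path Checkpoint path written by [run_training()].
#' @return A `tsegan_generator` with restored weights.
#' @export
load_generator <- function(path) {
  st <- load_checkpoint(path)
  gen <- init_generator(st$net_config)
  restore_params(gen, st$params$gen)
  gen
}
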