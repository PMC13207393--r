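#' DNA synthesis/sequencing noise model
#'
#' Independent per-base error events at configurable rates: a base is deleted
#' with `del_rate`, otherwise substituted with `sub_rate` by a uniformly
#' chosen *different* base; after every input position an extra uniform base
#' is inserted with `ins_rate`.  Real synthesis and sequencing workflows sit
#' around 0.5-2% combined; the simulator sweeps well beyond that.  The model
#' is seeded so every corruption is replayable.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities; their sum must
#'   not exceed 1.
#' @param seed Integer RNG seed recorded with the model.
#' @return A `channel_model` object.
#' @export
channel_model <- function(sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1)
    stop_helix("config", "rates must be probabilities with sum <= 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = as.integer(seed)),
            class = "channel_model")
}

#' Pass a sequence through the noisy channel
#'
#' @param seq A [nuc_seq()].
#' @param model A [channel_model()].
#' @return The corrupted [nuc_seq()] over the same alphabet.
#' @examples
#' m <- channel_model(sub_rate = 0.1, seed = 42)
#' corrupt(nuc_seq("ACGUACGUACGU", "RNA"), m)
#' @export
corrupt <- function(seq, model) {
  stopifnot(inherits(model, "channel_model"))
  ints <- seq_ints(seq)
  n <- length(ints)
  if (n == 0L) return(seq)
  out <- with_seed(model$seed, {
    u <- stats::runif(n)
    del <- u < model$del_rate
    sub <- !del & u < model$del_rate + model$sub_rate
    if (any(sub))
      ints[sub] <- (ints[sub] + sample(1:3, sum(sub), replace = TRUE)) %% 4L
    ins <- stats::runif(n) < model$ins_rate
    ins_base <- if (any(ins)) sample(0:3, sum(ins), replace = TRUE) else integer(0)
    cnt <- as.integer(!del) + as.integer(ins)
    prev <- cumsum(cnt) - cnt
    res <- integer(sum(cnt))
    res[prev[!del] + 1L] <- ints[!del]
    res[prev[ins] + as.integer(!del[ins]) + 1L] <- ins_base
    res
  })
  ints_to_seq(out, seq_alphabet(seq))
}

# evaluate code under a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}
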