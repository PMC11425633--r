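#' The seven swallowing-status classes
#'
#' Fixed class roster and ordering used throughout the package: resting
#' baseline, three bolus consistencies (thin liquid, soft food such as
#' apple sauce or pudding, dense food such as crackers), silent aspiration,
#' cough, and chewing.  The ordering is load-bearing: one-hot vectors,
#' confusion-matrix axes and the classifier output layer all use it.
#'
#' @return Character vector of length 7.
#' @export
swallow_classes <- function() {
  c("rest", "liquid", "soft_food", "dense_food",
    "silent_aspiration", "cough", "chewing")
}

# consistency classes share a common generative skeleton
.normal_swallow_classes <- c("liquid", "soft_food", "dense_food")

assert_class_label <- function(label) {
  if (length(label) != 1L || !is.character(label) ||
      !(label %in% swallow_classes())) {
    stop("unknown class label '", paste(label, collapse = ","),
         "'; valid labels: ", paste(swallow_classes(), collapse = ", "),
         call. = FALSE)
  }
  invisible(label)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Keeps simulator/trainer determinism
# independent of surrounding RNG use.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

rms <- function(x) sqrt(mean(x^2))

#' @useDynLib deglutio, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd
#' @importFrom utils modifyList head tail write.table read.table
NULL
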