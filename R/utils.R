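# internal helpers shared across modules

# classed errors so callers can distinguish schema, validation and config
# failures without matching on message text
stop2 <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "cypwaves_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

schemaError     <- function(fmt, ...) stop2("cypwaves_schema_error", fmt, ...)
validationError <- function(fmt, ...) stop2("cypwaves_validation_error", fmt, ...)
configError     <- function(fmt, ...) stop2("cypwaves_config_error", fmt, ...)
usageError      <- function(fmt, ...) stop2("cypwaves_usage_error", fmt, ...)

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    configError("'seed' must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Pearson correlation that treats constant vectors as uncorrelated (r = 0)
# rather than undefined; keeps affinity arithmetic total on flat profiles
safeCor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# strip assembly-copy suffixes ("c1"/"c2") so both copies of a duplicated
# locus collapse to one distinct gene
baseGeneName <- function(x) sub("c[0-9]+$", "", x)

# population standard deviation (divisor n)
sdPop <- function(x) sqrt(mean((x - mean(x))^2))
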