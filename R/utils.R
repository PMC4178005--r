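## Internal utilities: seeded evaluation, sub-seed derivation, pair keys.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`
#' and restores the previous state, so package functions never disturb
#' the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-seed from a master seed and a string key.
## Polynomial rolling hash mod a Mersenne prime; result fits a 32-bit
## signed integer so it can feed set.seed() directly.
subSeed <- function(seed, key) {
  p <- 2147483647
  h <- as.double(seed %% p)
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 131 + ch) %% p
  }
  as.integer(h)
}

## Canonical key for an unordered gene pair.
pairKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "||"), paste(b, a, sep = "||"))
}

## Split a pair key back into the two genes.
splitPairKey <- function(key) {
  strsplit(key, "||", fixed = TRUE)
}

## Effect labels allowed on interaction edges.
effectLevels <- function() c("activating", "inhibiting", "undefined")

## Stop unless all values are allowed effect labels.
checkEffects <- function(x) {
  bad <- setdiff(unique(x), effectLevels())
  if (length(bad) > 0L) {
    stop("unknown effect label(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
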