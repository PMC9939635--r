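#' Component label for a metal/medium pair
#'
#' Labels follow the convention used for multi-media mixtures: first letter
#' is the medium (B blood, U urine, H hair, S saliva), then the metal symbol,
#' e.g. `"UPb"` for urinary lead.
#'
#' @param metal Character vector of metal symbols (`"Mn"`, `"Pb"`, `"Cr"`, `"Cu"`).
#' @param medium Character vector of media (`"blood"`, `"urine"`, `"hair"`, `"saliva"`).
#' @return Character vector of component labels.
#' @examples
#' component_label("Pb", "urine")
#' @export
component_label <- function(metal, medium) {
  bad <- setdiff(unique(medium), MEDIA)
  if (length(bad)) stop("unknown medium: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(metal), METALS)
  if (length(bad)) stop("unknown metal: ", paste(bad, collapse = ", "))
  paste0(unname(MEDIUM_CODE[medium]), metal)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# All randomness flows from one root seed: child streams get their own
# integer seeds drawn deterministically from the root (kept < 2^31).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

is_simplex <- function(w, tol = 1e-8) {
  all(w >= -tol) && abs(sum(w) - 1) <= tol
}
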