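# Classed error conditions so callers (and the CLI) can react by type rather
# than by matching message text.

sp_stop <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("subpower_", subclass), "subpower_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

check_study_size <- function(study_size) {
  if (length(study_size) != 1L || !is.finite(study_size) ||
      study_size < 4 || study_size %% 2 != 0) {
    sp_stop("invalid_design",
            "`study_size` must be a single even integer >= 4 (total participants per study, both arms)")
  }
  invisible(as.integer(study_size))
}

check_i2 <- function(i2) {
  if (length(i2) != 1L || !is.finite(i2) || i2 < 0 || i2 >= 1) {
    sp_stop("domain", "`i2` must lie in [0, 1) on the proportion scale")
  }
  invisible(as.numeric(i2))
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    sp_stop("domain", "`alpha` must lie in (0, 1)")
  }
  invisible(as.numeric(alpha))
}

check_k <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k <= 0) {
    sp_stop("invalid_design", "`k` (number of studies) must be a positive number")
  }
  invisible(as.numeric(k))
}

check_subgroups <- function(effects, proportions) {
  p <- length(effects)
  if (p < 2L) {
    sp_stop("subgroup_spec", "at least two subgroups are required (`effects` has length < 2)")
  }
  if (length(proportions) != p) {
    sp_stop("subgroup_spec", "`effects` and `proportions` must have the same length")
  }
  if (any(!is.finite(proportions)) || any(proportions <= 0) || any(proportions >= 1)) {
    sp_stop("subgroup_spec", "each allocation proportion must lie strictly in (0, 1)")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    sp_stop("subgroup_spec", "proportions must sum to 1")
  }
  invisible(p)
}
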