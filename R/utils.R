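`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit sub-seed from a master seed and integer offsets.
derive_seed <- function(master, ...) {
  off <- c(...)
  s <- as.double(master) %% 2147483629
  for (o in off) s <- (s * 48271 + as.double(o) * 7919 + 1) %% 2147483629
  as.integer(s)
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) == 0L || all(x %in% c(0, 1))
}

check_genotype_values <- function(g, what = "genotype") {
  bad <- !(is.na(g) | g %in% c(0, 1, 2))
  if (any(bad)) {
    stop(sprintf("%s values must be 0, 1, 2 or NA; found %s",
                 what, paste(unique(g[bad])[1:min(3, sum(bad))], collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
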