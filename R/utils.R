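#' @keywords internal
#' @useDynLib coralclim, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Derive a reproducible 32-bit sub-seed from a base seed and an index.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(base_seed, index = 0L) {
  s <- (as.double(base_seed) * 1000003 + as.double(index)) %% 2147483629
  as.integer(s)
}

# Stop unless all conditions hold; `...` are named logical scalars whose
# names double as the error message.
stopifnot_named <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) {
    if (!isTRUE(all(conds[[nm]]))) stop(nm, call. = FALSE)
  }
  invisible(TRUE)
}

# Align an assemblage proportion matrix to a target taxon order,
# zero-filling taxa absent from `props`.
align_taxa <- function(props, taxa) {
  out <- matrix(0, nrow = nrow(props), ncol = length(taxa),
                dimnames = list(rownames(props), taxa))
  shared <- intersect(colnames(props), taxa)
  out[, shared] <- props[, shared, drop = FALSE]
  out
}

month_names <- paste0("sst_m", 1:12)

# Extract the cells x 12 monthly matrix from a clim_field data frame.
clim_months <- function(field) {
  as.matrix(field[, month_names, drop = FALSE])
}
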