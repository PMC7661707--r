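# Ground-truth metabolite source profiles for the synthetic MRSI generator.

# Peak templates: (center ppm, half-width ppm, default amplitude).
# Positions follow the short-TE murine glioblastoma literature: lactate and
# mobile-lipid signals around 1.3 ppm, alanine 1.47, NAA 2.02, glutamate +
# glutamine (Glx) 2.1-2.4, PUFA 2.8, creatine 3.03, choline 3.21,
# myo-inositol 3.55, glycine/Glx 3.75.
.peak_templates <- list(
  Lac  = c(center = 1.33, width = 0.030, amp = 1.00),
  Ala  = c(center = 1.47, width = 0.030, amp = 0.80),
  NAA  = c(center = 2.02, width = 0.035, amp = 0.90),
  Glx1 = c(center = 2.10, width = 0.045, amp = 0.70),
  Glx2 = c(center = 2.40, width = 0.045, amp = 0.65),
  PUFA = c(center = 2.80, width = 0.050, amp = 0.85),
  Cr   = c(center = 3.03, width = 0.030, amp = 0.75),
  Cho  = c(center = 3.21, width = 0.030, amp = 0.85),
  mI   = c(center = 3.55, width = 0.040, amp = 0.60),
  Gly  = c(center = 3.75, width = 0.045, amp = 0.55)
)

.lorentzian <- function(ppm, center, width, amp) {
  amp * width^2 / ((ppm - center)^2 + width^2)
}

#' Ground-truth spectral sources
#'
#' Builds `K` nonnegative source profiles on a shared, descending ppm axis.
#' Each profile is a sum of Lorentzian peaks at fixed metabolite positions
#' (Lac 1.33, Ala 1.47, Glx 2.1-2.4, PUFA 2.8 ppm, ...), normalized to unit
#' maximum. Every source carries a distinct characteristic peak so that no
#' two profiles coincide; remaining peak amplitudes are drawn from a seeded
#' uniform jitter. Source 1 is PUFA/Lac-rich (the "responding" pattern seen
#' after treatment), source 2 is Glx/Ala-rich (the untreated pattern); any
#' further sources cycle through the remaining metabolite templates.
#'
#' @param K number of sources (>= 2, at most the number of peak templates).
#' @param L spectrum length in points (>= 64).
#' @param ppm_range numeric length-2, chemical-shift range in ppm.
#' @param seed integer seed for the amplitude jitter.
#' @return an object of class `ground_truth_sources`: list with `ppm_axis`
#'   (descending), `profiles` (K x L nonnegative matrix, unit row maxima),
#'   and `peak_spec` (per-source data frame of center/width/amplitude).
#' @examples
#' gs <- make_sources(K = 2, L = 256, ppm_range = c(0.5, 4.5), seed = 1)
#' stopifnot(all(gs$profiles >= 0))
#' @export
make_sources <- function(K, L, ppm_range = c(0.5, 4.5), seed = 1L) {
  stopifnot(K >= 2, L >= 64, length(ppm_range) == 2)
  templates <- .peak_templates
  if (K > length(templates)) {
    stop("K = ", K, " exceeds the ", length(templates),
         " available distinct peak templates")
  }
  ppm_axis <- seq(max(ppm_range), min(ppm_range), length.out = L)
  set.seed(as.integer(seed))

  # characteristic peak per source: PUFA & Lac for source 1, Glx/Ala for
  # source 2, then round-robin over what is left
  char_sets <- vector("list", K)
  char_sets[[1]] <- c("PUFA", "Lac")
  char_sets[[2]] <- c("Glx1", "Glx2", "Ala")
  if (K > 2) {
    rest <- setdiff(names(templates), unlist(char_sets[1:2]))
    for (k in seq(3, K)) {
      char_sets[[k]] <- rest[((k - 3) %% length(rest)) + 1]
    }
  }

  profiles <- matrix(0, nrow = K, ncol = L)
  peak_spec <- vector("list", K)
  for (k in seq_len(K)) {
    main <- char_sets[[k]]
    # background peaks at reduced, jittered amplitude
    bg <- setdiff(names(templates), main)
    bg <- bg[stats::runif(length(bg)) < 0.6]
    specs <- lapply(c(main, bg), function(nm) {
      tm <- templates[[nm]]
      amp <- if (nm %in% main) tm["amp"] else tm["amp"] * stats::runif(1, 0.05, 0.25)
      c(center = unname(tm["center"]), width = unname(tm["width"]),
        amp = unname(amp))
    })
    spec_df <- do.call(rbind, specs)
    rownames(spec_df) <- c(main, bg)
    y <- rep(0, L)
    for (i in seq_len(nrow(spec_df))) {
      y <- y + .lorentzian(ppm_axis, spec_df[i, "center"],
                           spec_df[i, "width"], spec_df[i, "amp"])
    }
    profiles[k, ] <- y / max(y)
    peak_spec[[k]] <- as.data.frame(spec_df)
  }
  rownames(profiles) <- paste0("source", seq_len(K))
  structure(
    list(ppm_axis = ppm_axis, profiles = profiles, peak_spec = peak_spec),
    class = "ground_truth_sources"
  )
}

#' @export
print.ground_truth_sources <- function(x, ...) {
  cat("Ground-truth sources: K =", nrow(x$profiles),
      ", L =", ncol(x$profiles),
      sprintf(", ppm [%.2f, %.2f]\n",
              min(x$ppm_axis), max(x$ppm_axis)))
  invisible(x)
}
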