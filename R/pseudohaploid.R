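#' Call a pseudohaploid genome from a pileup
#'
#' At each panel site covered by at least one retained read, one read is
#' chosen uniformly at random and its base becomes the haploid call; sites
#' with no coverage are missing. Reads whose base matches neither panel
#' allele never produce calls. With `mask_transitions` every transition site
#' is set to missing afterwards, the standard guard against post-mortem
#' C-to-T / G-to-A deamination.
#'
#' @param pileup a [pileup_data] (already quality-filtered at ingestion).
#' @param panel the [snp_panel].
#' @param mask_transitions logical; code transition sites as missing.
#' @return A list of class `pseudohap` with `individual_id`, `calls`
#'   (integer vector over panel sites: 1 = allele1, 2 = allele2, NA =
#'   missing) and `mask_transitions`.
#' @export
call_pseudohaploid <- function(pileup, panel, mask_transitions = FALSE) {
  obs <- pileup$obs[pileup$obs$base != 3L, , drop = FALSE]
  calls <- rep(NA_integer_, nrow(panel))
  if (nrow(obs)) {
    perm <- sample.int(nrow(obs))
    obs <- obs[perm, , drop = FALSE]
    ord <- order(obs$site)   # stable: within a site, order is uniform random
    obs <- obs[ord, , drop = FALSE]
    first <- !duplicated(obs$site)
    calls[obs$site[first]] <- obs$base[first]
  }
  if (mask_transitions) calls[panel$mutation_class == "transition"] <- NA_integer_
  structure(list(individual_id = pileup$individual_id, calls = calls,
                 mask_transitions = mask_transitions),
            class = "pseudohap")
}

#' Build a pseudo-twin pair from one individual's pileup
#'
#' At each site with at least two retained reads, two distinct reads are
#' drawn uniformly without replacement; the first becomes twin A's call and
#' the second twin B's. The two resulting pseudohaploid genomes derive from
#' the same diploid individual and therefore behave as identical twins: their
#' mismatch rate estimates half the distance of an unrelated pair from the
#' same population, giving a reference-free kinship baseline.
#'
#' @inheritParams call_pseudohaploid
#' @return A list of class `pseudo_twins` with `individual_id`, `twin_a`,
#'   `twin_b` (both `pseudohap`) and `usable` (integer site indices where
#'   both twins are called, after any masking).
#' @export
make_pseudo_twins <- function(pileup, panel, mask_transitions = FALSE) {
  obs <- pileup$obs[pileup$obs$base != 3L, , drop = FALSE]
  a <- rep(NA_integer_, nrow(panel))
  b <- rep(NA_integer_, nrow(panel))
  if (nrow(obs)) {
    perm <- sample.int(nrow(obs))
    obs <- obs[perm, , drop = FALSE]
    obs <- obs[order(obs$site), , drop = FALSE]
    idx_in_site <- sequence(rle(obs$site)$lengths)
    multi <- obs$site %in% obs$site[idx_in_site == 2L]
    a[obs$site[multi & idx_in_site == 1L]] <- obs$base[multi & idx_in_site == 1L]
    b[obs$site[idx_in_site == 2L]] <- obs$base[idx_in_site == 2L]
  }
  if (mask_transitions) {
    ts <- panel$mutation_class == "transition"
    a[ts] <- NA_integer_
    b[ts] <- NA_integer_
  }
  twin <- function(calls, tag) {
    structure(list(individual_id = paste0(pileup$individual_id, tag),
                   calls = calls, mask_transitions = mask_transitions),
              class = "pseudohap")
  }
  structure(list(individual_id = pileup$individual_id,
                 twin_a = twin(a, ".twinA"), twin_b = twin(b, ".twinB"),
                 usable = which(!is.na(a) & !is.na(b))),
            class = "pseudo_twins")
}

#' @export
print.pseudohap <- function(x, ...) {
  cat(sprintf("<pseudohap> %s: %d called sites%s\n", x$individual_id,
              sum(!is.na(x$calls)),
              if (x$mask_transitions) " (transitions masked)" else ""))
  invisible(x)
}

#' @export
print.pseudo_twins <- function(x, ...) {
  cat(sprintf("<pseudo_twins> %s: %d usable sites (>=2 reads)\n",
              x$individual_id, length(x$usable)))
  invisible(x)
}

#' Write pseudohaploid calls as TSV
#' @param ph a `pseudohap` object.
#' @param panel the [snp_panel].
#' @param path output file; columns snp_id, call (allele character or `.`).
#' @return `path`, invisibly.
#' @export
write_pseudohaploid <- function(ph, panel, path) {
  call_chr <- rep(".", nrow(panel))
  call_chr[which(ph$calls == 1L)] <- panel$allele1[which(ph$calls == 1L)]
  call_chr[which(ph$calls == 2L)] <- panel$allele2[which(ph$calls == 2L)]
  writeLines(c("#snp_id\tcall",
               sprintf("%s\t%s", panel$snp_id, call_chr)), path)
  invisible(path)
}
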