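# Independent oracles and tiny fixture builders shared across tests.

# Expected phenotype fractions under the three-allele null (deletion)
# model, straight from the trinomial expansion of (p + q + r)^2:
# carriers of one null copy look homozygous, null homozygotes are
# no-calls. Fractions are relative to the total sample (they sum to
# 1 - r^2 over the called classes).
nullModelFractions <- function(p, q, r) {
    stopifnot(abs(p + q + r - 1) < 1e-12)
    list(pO = p^2 + 2 * p * r, qO = q^2 + 2 * q * r, pqO = 2 * p * q,
        noCall = r^2)
}

# Expected fractions under the gain model: the duplicated haplotype
# carries both SNP alleles so every carrier is heterozygote-like.
gainModelFractions <- function(p, q, g) {
    stopifnot(abs(p + q + g - 1) < 1e-12)
    list(pO = p^2, qO = q^2, pqO = 1 - p^2 - q^2, noCall = 0)
}

# GenotypeCounts from one or more count quadruples.
makeCounts <- function(..., map = NULL) {
    rows <- list(...)
    cnt <- do.call(rbind, rows)
    colnames(cnt) <- c("nAA", "nAB", "nBB", "nNoCall")
    if (is.null(rownames(cnt)))
        rownames(cnt) <- paste0("m", seq_len(nrow(cnt)))
    genotypeCounts(cnt, map)
}

# A small marker map data.frame.
tinyMap <- function(ids, chromosome = "1", position = NULL) {
    data.frame(markerId = ids,
        chromosome = rep_len(chromosome, length(ids)),
        position = if (is.null(position))
            seq(1000L, by = 50000L, length.out = length(ids))
        else position)
}

tmpWrite <- function(lines, ext = ".txt") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}
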