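# Small shared fixtures; everything is built in code at test time.

# tiny rectangular domain for field contracts
tiny_mask <- function(L = 2, h = 0.5) build_mask(shape_rectangle(L, L), h = h)

# write an 8-bit binary PGM (P5); img is a numeric matrix in [0, 1],
# row 1 = top row of the image
write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), "255"), con)
  writeBin(as.raw(round(255 * as.vector(t(img)))), con, size = 1L)
}

# constant-field state for cluster-level tests
const_state <- function(mask, ip3, ca) {
  structure(list(mask = mask, ip3 = rep(ip3, mask$n), ca = rep(ca, mask$n),
                 t = 0), class = "field_state")
}
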