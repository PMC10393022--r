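# fixture builders shared across test files; everything is generated in code

# small literal count matrix
tiny_counts <- function(values = c(5, 0, 7, 4, 4, 4),
                        proteins = c("P1", "P2"),
                        samples = c("s1", "s2", "s3")) {
  spectral_counts(matrix(values, nrow = length(proteins), byrow = TRUE,
                         dimnames = list(proteins, samples)))
}

# sheet with n primed_control/treated pairs plus vehicle and extract triplicates
tiny_sheet <- function(timepoint = "4h", n = 3L) {
  tag <- sub("h$", "", timepoint)
  rows <- lapply(seq_len(n), function(r) data.frame(
    sample_id = sprintf(c("VC%s_%d", "EX%s_%d", "PC%s_%d", "TR%s_%d"), tag, r),
    condition = c("vehicle_control", "extract", "primed_control", "treated"),
    timepoint = timepoint, replicate = r,
    pair_id = c("", "", sprintf("p%s_%d", tag, r), sprintf("p%s_%d", tag, r)),
    stringsAsFactors = FALSE))
  sample_sheet(do.call(rbind, rows))
}

# hand-built one-timepoint experiment with known classification outcomes:
#   ODF1-3     reference anchors, high and flat, absent from the extract
#   EXTONLY    zero in both sperm controls, present in extract + treated (class 1)
#   GOUP       present everywhere, treated ~3x control    (class 2)
#   GODOWN     present everywhere, treated ~1/3 control   (class 3)
#   FLAT1-4    present everywhere, replicate noise only   (unclassified)
#   GHOST      never detected anywhere (must be omitted)
# GOUP's gain (~+62) and GODOWN's loss (~-65) offset, so the mean-scaling
# stage stays near-neutral and the flats keep their null differences.
handmade_experiment <- function() {
  sheet <- tiny_sheet("4h")
  samples <- sheet$sample_id
  prot <- c("ODF1", "ODF2", "ODF3", "EXTONLY", "GOUP", "GODOWN",
            paste0("FLAT", 1:4), "GHOST")
  m <- matrix(0, length(prot), length(samples),
              dimnames = list(prot, samples))
  flat_base <- c(FLAT1 = 20, FLAT2 = 35, FLAT3 = 50, FLAT4 = 65)
  flat_pc <- list(c(-2, 1, 2), c(3, -1, -2), c(0, 4, -3), c(-4, 0, 3))
  flat_tr <- list(c(1, -3, 2), c(-2, 2, 1), c(3, -4, 0), c(2, 1, -3))
  for (r in 1:3) {
    vc <- sprintf("VC4_%d", r); ex <- sprintf("EX4_%d", r)
    pc <- sprintf("PC4_%d", r); tr <- sprintf("TR4_%d", r)
    m[c("ODF1", "ODF2", "ODF3"), c(vc, pc, tr)] <- 200 + 10 * r
    m["EXTONLY", c(ex, tr)] <- c(40, 38 + r)
    m["GOUP", c(vc, ex, pc, tr)] <- c(30, 30, c(28, 31, 29)[r], c(85, 100, 93)[r])
    m["GODOWN", c(vc, ex, pc, tr)] <- c(90, 90, c(88, 93, 90)[r], c(24, 28, 25)[r])
    for (k in 1:4) {
      b <- flat_base[k]
      m[paste0("FLAT", k), c(vc, ex, pc, tr)] <-
        c(b, b, b + flat_pc[[k]][r], b + flat_tr[[k]][r])
    }
  }
  list(counts = spectral_counts(m), sheet = sheet)
}

# assignment table shaped like assign_classes() output, for inventory tests
fake_assignments <- function(ids, klass, timepoint,
                             thresholds = significance_thresholds()) {
  if (!length(ids)) {
    out <- data.frame(protein_id = character(0), timepoint = character(0),
                      klass = character(0), p_value = numeric(0),
                      direction = character(0), admitted_alpha = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "thresholds") <- thresholds
    return(out)
  }
  out <- data.frame(protein_id = ids, timepoint = timepoint, klass = klass,
                    p_value = ifelse(klass == "unclassified", 0.5, 0.01),
                    direction = "increase",
                    admitted_alpha = ifelse(klass == "unclassified", NA, 0.1),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}
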