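# small builders shared across tests

mk_calls <- function(starts, ends, svtype = "DEL", sample = "S1",
                     caller = "cnvnator", chrom = "groupI") {
  data.frame(chrom = chrom, start = starts, end = ends,
             svtype = svtype, sample = sample, caller = caller,
             stringsAsFactors = FALSE)
}

mk_manifest <- function() {
  cnv_manifest(data.frame(
    sample = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    population = c("Ca_L", "Ca_L", "Ca_R", "Ca_R", "Us_R", "Us_R", "No_L", "No_L"),
    country = c("Ca", "Ca", "Ca", "Ca", "Us", "Us", "No", "No"),
    continent = c("Pacific", "Pacific", "Pacific", "Pacific",
                  "Pacific", "Pacific", "Atlantic", "Atlantic"),
    ecotype = c("lake", "lake", "river", "river", "river", "river",
                "lake", "lake"),
    stringsAsFactors = FALSE
  ))
}

mk_layout <- function() {
  genome_layout(c(groupI = 1e6, groupII = 1e6, groupXIX = 5e5))
}

# random call set on one chromosome for property tests
random_calls <- function(n, sample = "S1", caller = "cnvnator",
                         svtype = "DEL", max_pos = 50000) {
  s <- sort(sample.int(max_pos, n))
  len <- sample(200:3000, n, replace = TRUE)
  mk_calls(s, s + len, svtype = svtype, sample = sample, caller = caller)
}
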