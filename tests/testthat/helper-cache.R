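# Expensive shared objects (EPG correction tables, DAM lookup) built
# once per test run.
.vfat1_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.vfat1_cache[[key]])) .vfat1_cache[[key]] <- builder()
  .vfat1_cache[[key]]
}

get_dam_lookup <- function() {
  cached("dam_lookup", function() build_dam_lookup())
}

get_corr_phantom <- function() {
  cached("corr45", function() {
    build_spoiling_correction(t2 = 45, tr = 4.1)
  })
}
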