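# shared fixtures: built in code, no files

# balanced record table across the three categories
balancedRecords <- function(nPerClass = 20, seed = 1) {
  do.call(rbind, lapply(1:3, function(k)
    sampleFeatures(k, nPerClass, seed = seed + k - 1L)))
}

# a record pinned at a category's profile means
meanRecord <- function(category) {
  rec <- sampleFeatures(category, 1, seed = 1)
  prof <- categoryProfiles(category)
  for (p in featureNames()) rec[[p]] <- prof[[paste0(p, "_mean")]]
  rec
}

# constant-colour ImageSample with an all-TRUE mask
flatImage <- function(r, g, b, side = 10) {
  px <- array(0L, c(side, side, 3))
  px[, , 1] <- as.integer(r); px[, , 2] <- as.integer(g)
  px[, , 3] <- as.integer(b)
  ImageSample(px)
}
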