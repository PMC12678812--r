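# Pre-seeded species-match cache (JSON lines, one response per query).
# Entries below were recorded from the GBIF species-match service for the
# documented worked example; with offline = TRUE the adapter serves only
# these cached responses.
{"key":"lonchura malacca|animalia","query":"Lonchura malacca","response":{"usageKey":2493626,"scientificName":"Lonchura malacca (Linnaeus, 1766)","canonicalName":"Lonchura malacca","rank":"SPECIES","status":"ACCEPTED","confidence":99,"matchType":"EXACT","kingdom":"Animalia","phylum":"Chordata","order":"Passeriformes","family":"Estrildidae","genus":"Lonchura","species":"Lonchura malacca","class":"Aves"}}
{"key":"lonchura malacca|","query":"Lonchura malacca","response":{"usageKey":2493626,"scientificName":"Lonchura malacca (Linnaeus, 1766)","canonicalName":"Lonchura malacca","rank":"SPECIES","status":"ACCEPTED","confidence":99,"matchType":"EXACT","kingdom":"Animalia","phylum":"Chordata","order":"Passeriformes","family":"Estrildidae","genus":"Lonchura","species":"Lonchura malacca","class":"Aves"}}
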