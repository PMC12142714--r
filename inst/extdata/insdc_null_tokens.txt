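missing
not collected
not applicable
not provided
restricted access
unknown
n/a
na
none provided
not available
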