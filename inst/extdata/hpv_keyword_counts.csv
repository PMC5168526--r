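keyword,n,denominator
HPV,191515,216060
HPV vaccine,75433,216060
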