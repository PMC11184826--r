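{"fs":100,"events":{"FF":11,"HO":22,"TO":33,"HS":77}}
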