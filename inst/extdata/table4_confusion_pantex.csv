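predicted,actual,count
building,building,86
building,non_building,55
non_building,building,100
non_building,non_building,333
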