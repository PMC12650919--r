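sample_id,v_pre,v_pre_err,v_post,v_post_err
Sample 1,19734.1,1094.5,19521.9,1126.5
Sample 2,18990.2,1004.6,18087.4,1006.8
Sample 3,15959.7,933.9,14552.6,899.6
Sample 4,20756.2,1111.5,18313.2,1098.9
Sample 5,10525.6,420.2,8083.3,510.9
Sample 6,10860.4,750.4,8197.4,430.2
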