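name_kana,sex,birthday,address,option,digest
yamada tarou,m,1970-01-02,tokyo nakano 4-21-1,D,23489f4231a44410c3a5bcaf243cc2a7f0ca9284d79635a978580cd34d3e85af
ヤマダ　タロウ,f,1955-12-31,ＯＳＡＫＡ,D,522bbf7f32dc11e8e55da39591b000a88a461ee43bcf307aaacf7991de83ad76
suzuki hanako,f,1960-06-15,kyoto,E,6962bb8f328aa68276c8fd65f6d1e64369b1aad5a97318a02bfa5d7682dcf853
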