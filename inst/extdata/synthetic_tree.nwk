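((OTU_1:0.8095298512,((OTU_2:0.6637080223,((OTU_3:0.3684790863,OTU_4:0.2457898974):0.6505609236,(OTU_5:0.5591847091,(OTU_6:0.4770138056,OTU_7:0.9355346218):0.4803555801):0.2986037112):0.09217625624):0.4744932612,(OTU_8:0.6781966412,OTU_9:0.9344652041):0.4701776237):0.5447696743):0.2606451984,((((OTU_10:0.1673598858,OTU_11:0.4690716881):0.8755772659,OTU_12:0.6522297396):0.3133020622,((((OTU_13:0.6188615733,(OTU_14:0.1006342026,OTU_15:0.227715387):0.9562933391):0.4589058443,((OTU_16:0.4796690829,OTU_17:0.8810373074):0.7710296435,((OTU_18:0.8668611001,OTU_19:0.5602835801):0.6904980401,OTU_20:0.3045441357):0.9679976783):0.5550137623):0.1497643588,OTU_21:0.9992875529):0.435452316,(((((OTU_22:0.9830397551,(((OTU_23:0.9883801525,OTU_24:0.7654968186):0.9111781656,(OTU_25:0.9397345618,((OTU_26:0.7622901241,OTU_27:0.4863328848):0.9074923156,OTU_28:0.2502086856):0.6716269818):0.8205272416):0.7428410652,(((OTU_29:0.1062347332,OTU_30:0.611033974):0.2357115769,(OTU_31:0.2146104232,OTU_32:0.01649174467):0.2046970029):0.008593605133,OTU_33:0.3281943654):0.3590447174):0.5021491409):0.6810901957,(OTU_34:0.9138724054,OTU_35:0.4178718044):0.2695952761):0.5985257931,(OTU_36:0.900012892,(OTU_37:0.4610331599,OTU_38:0.6056756775):0.2077089292):0.690565649):0.04191105673,(OTU_39:0.2768555577,(OTU_40:0.9835575758,(OTU_41:0.8795516968,OTU_42:0.2334594787):0.09838715266):0.2261424325):0.5625974033):0.9033713706,(OTU_43:0.4718593394,OTU_44:0.4088482491):0.7723960734):0.2932616444):0.03446071269):0.9473770969,(((OTU_45:0.01449069218,OTU_46:0.6428237623):0.4912112271,(OTU_47:0.5343920058,(OTU_48:0.04039345798,OTU_49:0.2850443337):0.9540982328):0.3203817445):0.534970935,(((OTU_50:0.4376300778,OTU_51:0.186323558):0.4383082271,(OTU_52:0.1453450485,OTU_53:0.778950528):0.9454489965):0.4813590271,(((OTU_54:0.2641242412,OTU_55:0.5218471647):0.3165819882,(OTU_56:0.6531599234,OTU_57:0.2772224462):0.2031900745):0.2201669943,(OTU_58:0.8367246841,(OTU_59:0.2541121149,OTU_60:0.8560147309):0.435053162):0.408674475):0.8133833895):0.4917698111):0.8232231706):0.2739994512);
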